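# Minimal tape-based reverse-mode automatic differentiation for the graph
# networks (WLN, GCN, attentive classifier). Nodes hold dense matrices; the
# op set is exactly what message passing, attention and the BCE-with-logits
# loss require. Single-threaded and deterministic given the RNG seed.

.nn <- new.env(parent = emptyenv())
.nn$tape <- NULL

nn_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  .nn$tape <- t
  invisible(t)
}

nd_record <- function(node) {
  t <- .nn$tape
  if (!is.null(t)) t$nodes[[length(t$nodes) + 1L]] <- node
  node
}

nd_new <- function(val, parents = list(), backfn = NULL, requires = TRUE) {
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$parents <- parents
  node$backfn <- backfn
  node$requires <- requires
  nd_record(node)
}

nd_const <- function(x) nd_new(as.matrix(x), requires = FALSE)
nd_param <- function(x) nd_new(as.matrix(x), requires = TRUE)

nd_val <- function(a) a$val

acc_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

# ops ------------------------------------------------------------------------

nd_matmul <- function(a, b, transpose_b = FALSE) {
  v <- if (transpose_b) a$val %*% t(b$val) else a$val %*% b$val
  nd_new(v, list(a, b), function(g) {
    if (transpose_b) {
      acc_grad(a, g %*% b$val)
      acc_grad(b, t(g) %*% a$val)
    } else {
      acc_grad(a, g %*% t(b$val))
      acc_grad(b, t(a$val) %*% g)
    }
  })
}

# addition with row-vector (bias) broadcasting
nd_add <- function(a, b) {
  av <- a$val; bv <- b$val
  if (nrow(bv) == 1L && nrow(av) > 1L) {
    v <- sweep(av, 2, as.numeric(bv), "+")
    nd_new(v, list(a, b), function(g) {
      acc_grad(a, g)
      acc_grad(b, matrix(colSums(g), 1L))
    })
  } else if (nrow(av) == 1L && nrow(bv) > 1L) {
    nd_add(b, a)
  } else {
    nd_new(av + bv, list(a, b), function(g) {
      acc_grad(a, g); acc_grad(b, g)
    })
  }
}

nd_mul <- function(a, b) {          # elementwise, same shape
  nd_new(a$val * b$val, list(a, b), function(g) {
    acc_grad(a, g * b$val); acc_grad(b, g * a$val)
  })
}

nd_scale <- function(a, s) {        # s plain numeric scalar
  nd_new(a$val * s, list(a), function(g) acc_grad(a, g * s))
}

nd_relu <- function(a) {
  m <- a$val > 0
  nd_new(a$val * m, list(a), function(g) acc_grad(a, g * m))
}

nd_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$val))
  nd_new(s, list(a), function(g) acc_grad(a, g * s * (1 - s)))
}

nd_tanh <- function(a) {
  s <- tanh(a$val)
  nd_new(s, list(a), function(g) acc_grad(a, g * (1 - s^2)))
}

nd_exp <- function(a) {
  e <- exp(a$val)
  nd_new(e, list(a), function(g) acc_grad(a, g * e))
}

nd_reciprocal <- function(a) {
  r <- 1 / a$val
  nd_new(r, list(a), function(g) acc_grad(a, -g * r^2))
}

# numerically stable softmax within segments (rows grouped by `seg`)
nd_softmax_by <- function(a, seg, nseg) {
  shift <- tapply(as.numeric(a$val), seg, max)[as.character(seg)]
  e <- nd_exp(nd_add(a, nd_const(matrix(-shift, ncol = 1L))))
  denom <- nd_rowsum_by(e, seg, nseg)
  nd_mul(e, nd_rows(nd_reciprocal(denom), seg))
}

nd_concat_cols <- function(...) {
  xs <- list(...)
  widths <- vapply(xs, function(x) ncol(x$val), integer(1))
  v <- do.call(cbind, lapply(xs, nd_val))
  nd_new(v, xs, function(g) {
    at <- 0L
    for (t in seq_along(xs)) {
      acc_grad(xs[[t]], g[, at + seq_len(widths[t]), drop = FALSE])
      at <- at + widths[t]
    }
  })
}

nd_rbind <- function(xs) {
  if (length(xs) == 1L) return(xs[[1]])
  heights <- vapply(xs, function(x) nrow(x$val), integer(1))
  v <- do.call(rbind, lapply(xs, nd_val))
  nd_new(v, xs, function(g) {
    at <- 0L
    for (t in seq_along(xs)) {
      acc_grad(xs[[t]], g[at + seq_len(heights[t]), , drop = FALSE])
      at <- at + heights[t]
    }
  })
}

# row gather; backward is scatter-add
nd_rows <- function(a, idx) {
  nd_new(a$val[idx, , drop = FALSE], list(a), function(g) {
    da <- matrix(0, nrow(a$val), ncol(a$val))
    s <- rowsum(g, group = idx)
    da[as.integer(rownames(s)), ] <- s
    acc_grad(a, da)
  })
}

# per-group row sums; groups in 1..ngroups
nd_rowsum_by <- function(a, groups, ngroups) {
  v <- matrix(0, ngroups, ncol(a$val))
  s <- rowsum(a$val, group = groups)
  v[as.integer(rownames(s)), ] <- s
  nd_new(v, list(a), function(g) acc_grad(a, g[groups, , drop = FALSE]))
}

# per-group column-wise max (readout max-pool); argmax rows get the gradient
nd_maxpool_by <- function(a, groups, ngroups) {
  nc <- ncol(a$val)
  v <- matrix(-Inf, ngroups, nc)
  arg <- matrix(NA_integer_, ngroups, nc)
  for (r in seq_len(nrow(a$val))) {
    gr <- groups[r]
    upd <- a$val[r, ] > v[gr, ]
    v[gr, upd] <- a$val[r, upd]
    arg[gr, upd] <- r
  }
  nd_new(v, list(a), function(g) {
    da <- matrix(0, nrow(a$val), nc)
    for (gr in seq_len(ngroups)) for (j in seq_len(nc)) {
      r <- arg[gr, j]
      if (!is.na(r)) da[r, j] <- da[r, j] + g[gr, j]
    }
    acc_grad(a, da)
  })
}

nd_softmax_rows <- function(a) {
  z <- a$val - apply(a$val, 1, max)
  e <- exp(z)
  s <- e / rowSums(e)
  nd_new(s, list(a), function(g) {
    dot <- rowSums(g * s)
    acc_grad(a, (g - dot) * s)
  })
}

nd_sum <- function(a) {
  nd_new(matrix(sum(a$val), 1L, 1L), list(a), function(g) {
    acc_grad(a, matrix(as.numeric(g), nrow(a$val), ncol(a$val)))
  })
}

# Numerically stable binary cross-entropy with logits, mean over elements.
nd_bce_logits <- function(logits, y) {
  z <- logits$val
  n <- length(z)
  l <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  nd_new(matrix(l, 1L, 1L), list(logits), function(g) {
    s <- 1 / (1 + exp(-z))
    acc_grad(logits, matrix((s - y) / n, nrow(z), ncol(z)) *
               as.numeric(g))
  })
}

# backward -------------------------------------------------------------------

nn_backward <- function(loss) {
  t <- .nn$tape
  if (is.null(t)) stop_ugtsom("nn", "no active tape")
  loss$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_along(t$nodes))) {
    node <- t$nodes[[i]]
    if (!is.null(node$grad) && !is.null(node$backfn)) node$backfn(node$grad)
  }
  invisible(NULL)
}

# parameter store ------------------------------------------------------------

# Glorot-uniform initialization; `dims` is a named list of c(rows, cols).
nn_init_params <- function(dims, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (nm in names(dims)) {
    d <- dims[[nm]]
    if (grepl("^b_", nm)) {
      out[[nm]] <- matrix(0, d[1], d[2])
    } else {
      lim <- sqrt(6 / (d[1] + d[2]))
      out[[nm]] <- matrix(stats::runif(d[1] * d[2], -lim, lim), d[1], d[2])
    }
  }
  out
}

nn_wrap_params <- function(theta) lapply(theta, nd_param)

nn_collect_grads <- function(pnodes) {
  lapply(pnodes, function(p) {
    if (is.null(p$grad)) matrix(0, nrow(p$val), ncol(p$val)) else p$grad
  })
}

# Adam -----------------------------------------------------------------------

adam_init <- function(theta) {
  list(m = lapply(theta, function(x) x * 0),
       v = lapply(theta, function(x) x * 0),
       t = 0L)
}

adam_step <- function(theta, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(theta)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    theta[[nm]] <- theta[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(theta = theta, state = state)
}

# early stopping --------------------------------------------------------------

#' Early-stopping policy for gradient-trained models
#'
#' Training halts at the first satisfied criterion: the epoch cap, no
#' improvement of the training metric for `patience_train` epochs, or no
#' improvement of the validation metric for `patience_valid` epochs.
#'
#' @param max_epochs epoch cap (default 500).
#' @param patience_train epochs without training-metric improvement (10).
#' @param patience_valid epochs without validation-metric improvement (15).
#' @export
early_stop_policy <- function(max_epochs = 500L, patience_train = 10L,
                              patience_valid = 15L) {
  stopifnot(max_epochs >= 1L, patience_train >= 1L, patience_valid >= 1L)
  structure(list(max_epochs = as.integer(max_epochs),
                 patience_train = as.integer(patience_train),
                 patience_valid = as.integer(patience_valid)),
            class = "early_stop_policy")
}

# Stateful tracker: call update(train_metric, valid_metric) per epoch
# (metrics oriented so higher is better); returns TRUE when training should
# stop.
early_stop_tracker <- function(policy) {
  best_tr <- -Inf; best_va <- -Inf
  since_tr <- 0L; since_va <- 0L; epoch <- 0L
  list(
    update = function(train_metric, valid_metric) {
      epoch <<- epoch + 1L
      if (train_metric > best_tr + 1e-12) {
        best_tr <<- train_metric; since_tr <<- 0L
      } else since_tr <<- since_tr + 1L
      if (valid_metric > best_va + 1e-12) {
        best_va <<- valid_metric; since_va <<- 0L
      } else since_va <<- since_va + 1L
      epoch >= policy$max_epochs ||
        since_tr >= policy$patience_train ||
        since_va >= policy$patience_valid
    },
    improved_valid = function() since_va == 0L,
    epoch = function() epoch
  )
}
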