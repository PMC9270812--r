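# Weisfeiler-Lehman network for site-of-glucuronidation prediction.
#
# A reaction graph contains the substrate plus the glucuronosyl co-reactant.
# Atom features are refined by iterated neighbor/bond merging (the WL
# update); a global attention step over all reactant atoms yields a context
# vector per atom; the reactivity of each candidate site is scored from the
# concatenated (local, context) features of the site atom and the anomeric
# carbon through a feed-forward pair head. Training minimizes binary
# cross-entropy with logits over (site, anomeric) pairs, with the true SOM
# as the positive and the substrate's other candidate sites as negatives.

#' WLN configuration
#'
#' @param n_wl_iterations WL refinement rounds (>= 1; 1 works best for
#'   glucuronidation data and is the default).
#' @param hidden_width width of atom embeddings and the pair head.
#' @param learning_rate Adam learning rate.
#' @param batch_size reactions per mini-batch.
#' @param early_stop an [early_stop_policy()].
#' @param seed integer seed controlling initialization and batch order.
#' @export
wln_config <- function(n_wl_iterations = 1L, hidden_width = 128L,
                       learning_rate = 0.001, batch_size = 20L,
                       early_stop = early_stop_policy(), seed = 1L) {
  stopifnot(n_wl_iterations >= 1L, learning_rate > 0, hidden_width >= 2L,
            batch_size >= 1L, inherits(early_stop, "early_stop_policy"))
  structure(list(n_wl_iterations = as.integer(n_wl_iterations),
                 hidden_width = as.integer(hidden_width),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 early_stop = early_stop, seed = as.integer(seed)),
            class = "wln_config")
}

wln_param_dims <- function(d_in, d_edge, d) {
  list(
    W_atom = c(d_in, d), b_atom = c(1L, d),
    W_nei = c(d, d), W_edge = c(d_edge, d), b_msg = c(1L, d),
    W_self = c(d, d), W_agg = c(d, d), b_upd = c(1L, d),
    Wq = c(d, d), Wk = c(d, d), Wv = c(d, d),
    W_pair = c(4L * d, d), b_pair = c(1L, d),
    w_out = c(d, 1L), b_out = c(1L, 1L)
  )
}

# Reaction graph: substrate atoms first, then the glucuronosyl co-reactant.
# `sites` are candidate atom indices (in substrate numbering == graph
# numbering); `anomeric` is the graph index of the anomeric carbon.
wln_reaction_graph <- function(substrate_mg, include_sugar = TRUE) {
  gsub <- mol_to_graph(substrate_mg, scheme = "wln")
  cand <- enumerate_candidate_sites(substrate_mg)
  n0 <- nrow(gsub$node_feats)
  if (include_sugar) {
    sg <- glucuronyl_molgraph()
    gsug <- mol_to_graph(sg$mg, scheme = "wln")
    X <- rbind(gsub$node_feats, gsug$node_feats)
    E <- rbind(gsub$edge_feats, gsug$edge_feats)
    edges <- rbind(gsub$edges, gsug$edges + n0)
    anomeric <- n0 + sg$anomeric
  } else {
    X <- gsub$node_feats; E <- gsub$edge_feats; edges <- gsub$edges
    anomeric <- NA_integer_
  }
  list(X = X, E = E, edges = edges, n_sub = n0, n = nrow(X),
       sites = cand$atom_index, site_class = cand$site_class,
       anomeric = anomeric)
}

# Directed edge view (each bond in both directions) for message passing.
directed_edges <- function(edges, E) {
  if (nrow(edges) == 0L)
    return(list(src = integer(0), dst = integer(0),
                E2 = matrix(0, 0L, ncol(E))))
  list(src = c(edges[, 1], edges[, 2]),
       dst = c(edges[, 2], edges[, 1]),
       E2 = rbind(E, E))
}

# Forward pass pieces (autodiff nodes) ---------------------------------------

wln_local_forward <- function(p, Xn, de, n, n_iter) {
  h <- nd_relu(nd_add(nd_matmul(Xn, p$W_atom), p$b_atom))
  if (length(de$src)) En <- nd_const(de$E2)
  for (t in seq_len(n_iter)) {
    if (length(de$src)) {
      msg <- nd_relu(nd_add(nd_add(nd_matmul(nd_rows(h, de$src), p$W_nei),
                                   nd_matmul(En, p$W_edge)), p$b_msg))
      m <- nd_rowsum_by(msg, de$dst, n)
      h <- nd_relu(nd_add(nd_add(nd_matmul(h, p$W_self),
                                 nd_matmul(m, p$W_agg)), p$b_upd))
    } else {
      h <- nd_relu(nd_add(nd_matmul(h, p$W_self), p$b_upd))
    }
  }
  h
}

# Scaled dot-product attention over the atoms listed in `idx` (one reaction);
# returns the context rows aligned with idx.
wln_attention_forward <- function(p, h, idx, d) {
  hi <- nd_rows(h, idx)
  Q <- nd_matmul(hi, p$Wq)
  K <- nd_matmul(hi, p$Wk)
  V <- nd_matmul(hi, p$Wv)
  S <- nd_scale(nd_matmul(Q, K, transpose_b = TRUE), 1 / sqrt(d))
  A <- nd_softmax_rows(S)
  list(context = nd_matmul(A, V), weights = A)
}

wln_pair_logits <- function(p, local_rows, ctx_rows, an_local, an_ctx) {
  f <- nd_concat_cols(local_rows, ctx_rows, an_local, an_ctx)
  hdn <- nd_relu(nd_add(nd_matmul(f, p$W_pair), p$b_pair))
  nd_add(nd_matmul(hdn, p$w_out), p$b_out)
}

# Full forward for a batch of prepared reaction graphs. Returns pair logits
# (node) plus bookkeeping of which logit belongs to which reaction/site.
wln_batch_forward <- function(theta, graphs, n_iter, d, negatives = NULL) {
  p <- nn_wrap_params(theta)
  offs <- cumsum(c(0L, vapply(graphs, `[[`, integer(1), "n")))
  X <- do.call(rbind, lapply(graphs, `[[`, "X"))
  E <- do.call(rbind, lapply(graphs, function(g) g$E))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(t)
    graphs[[t]]$edges + offs[t]))
  de <- directed_edges(edges, E)
  N <- nrow(X)
  h <- wln_local_forward(p, nd_const(X), de, N, n_iter)

  site_idx <- integer(0); an_idx <- integer(0)
  rxn_of <- integer(0); site_atom <- integer(0)
  ctx_parts <- vector("list", length(graphs))
  for (t in seq_along(graphs)) {
    g <- graphs[[t]]
    idx <- offs[t] + seq_len(g$n)
    ctx_parts[[t]] <- wln_attention_forward(p, h, idx, d)$context
    sites <- g$sites
    if (!is.null(negatives)) sites <- c(sites, negatives[[t]])
    if (length(sites)) {
      site_idx <- c(site_idx, offs[t] + sites)
      an_idx <- c(an_idx, rep(offs[t] + g$anomeric, length(sites)))
      rxn_of <- c(rxn_of, rep(t, length(sites)))
      site_atom <- c(site_atom, sites)
    }
  }
  # reactions are contiguous atom blocks, so stacking the per-reaction
  # context rows restores global atom order
  Cg <- nd_rbind(ctx_parts)
  logits <- wln_pair_logits(p, nd_rows(h, site_idx), nd_rows(Cg, site_idx),
                            nd_rows(h, an_idx), nd_rows(Cg, an_idx))
  list(logits = logits, p = p, rxn_of = rxn_of, site_atom = site_atom,
       h = h, context = Cg)
}

# Prepare a reaction record for training: graph + positive label vector.
wln_prepare_reaction <- function(rec) {
  sub <- rec$reactants[[rec$substrate_index]]
  g <- wln_reaction_graph(sub)
  g$labels <- as.integer(g$sites == rec$som_atom_index)
  if (!rec$som_atom_index %in% g$sites) {
    # true SOM outside the candidate enumeration: keep it as an extra site
    g$sites <- c(g$sites, rec$som_atom_index)
    g$site_class <- c(g$site_class, rec$som_class)
    g$labels <- c(g$labels, 1L)
  }
  g$true_sites <- rec$som_atom_index
  g$som_class <- rec$som_class
  g
}

wln_rank_batch <- function(theta, graphs, n_iter, d) {
  nn_tape()
  fw <- wln_batch_forward(theta, graphs, n_iter, d)
  .nn$tape <- NULL
  z <- as.numeric(nd_val(fw$logits))
  split(data.frame(atom = fw$site_atom, score = z), fw$rxn_of)
}

# top-1 accuracy of current parameters on prepared graphs
wln_eval_top1 <- function(theta, graphs, n_iter, d) {
  ranked <- wln_rank_batch(theta, graphs, n_iter, d)
  ok <- vapply(seq_along(graphs), function(t) {
    r <- ranked[[as.character(t)]]
    if (is.null(r)) return(0L)
    ord <- order(-r$score, r$atom)
    as.integer(r$atom[ord][1] %in% graphs[[t]]$true_sites)
  }, integer(1))
  mean(ok)
}

#' Train the WLN site-of-metabolism model
#'
#' @param reactions list of `reaction_record`s (training set).
#' @param config a [wln_config()].
#' @param validation optional list of `reaction_record`s monitored for early
#'   stopping (validation top-1); when `NULL` a seeded 10% split of
#'   `reactions` is held out.
#' @return a `wln_model`: parameters, config, and the per-epoch training log
#'   (`loss`, `valid_top1`).
#' @export
train_wln <- function(reactions, config = wln_config(), validation = NULL) {
  stopifnot(length(reactions) > 0L)
  if (is.null(validation)) {
    set.seed(config$seed)
    nv <- max(1L, floor(0.1 * length(reactions)))
    vi <- sample(seq_along(reactions), nv)
    validation <- reactions[vi]
    reactions <- reactions[-vi]
  }
  graphs <- lapply(reactions, wln_prepare_reaction)
  vgraphs <- lapply(validation, wln_prepare_reaction)
  d_in <- ncol(graphs[[1]]$X)
  d <- config$hidden_width
  theta <- nn_init_params(wln_param_dims(d_in, 6L, d),
                          seed = config$seed)

  # degenerate all-single-site data: no negative pairs anywhere
  n_sites <- vapply(graphs, function(g) length(g$sites), integer(1))
  negatives <- NULL
  if (all(n_sites <= 1L)) {
    warning("all training reactions have a single candidate site; ",
            "sampling carbon atoms as negative pairs", call. = FALSE)
    set.seed(config$seed + 1L)
    negatives <- lapply(graphs, function(g) {
      pool <- setdiff(seq_len(g$n_sub), g$sites)
      if (length(pool) == 0L) return(integer(0))
      sample(pool, min(3L, length(pool)))
    })
  }

  st <- adam_init(theta)
  tracker <- early_stop_tracker(config$early_stop)
  log_loss <- numeric(0); log_top1 <- numeric(0)
  best_theta <- theta; best_top1 <- -Inf
  set.seed(config$seed + 2L)
  for (epoch in seq_len(config$early_stop$max_epochs)) {
    ord <- sample(seq_along(graphs))
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      sel <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      nn_tape()
      fw <- wln_batch_forward(theta, graphs[sel], config$n_wl_iterations, d,
                              negatives = if (is.null(negatives)) NULL
                                          else negatives[sel])
      y <- unlist(lapply(seq_along(sel), function(t) {
        g <- graphs[[sel[t]]]
        lab <- g$labels
        if (!is.null(negatives))
          lab <- c(lab, rep(0L, length(negatives[[sel[t]]])))
        lab
      }))
      if (length(y) == 0L) next
      loss <- nd_bce_logits(fw$logits, matrix(y, ncol = 1L))
      if (!is.finite(nd_val(loss)))
        stop_ugtsom("divergence", "non-finite training loss at epoch ", epoch)
      nn_backward(loss)
      g <- nn_collect_grads(fw$p)
      .nn$tape <- NULL
      upd <- adam_step(theta, g, st, lr = config$learning_rate)
      theta <- upd$theta; st <- upd$state
      ep_loss <- ep_loss + nd_val(loss); nb <- nb + 1L
    }
    ep_loss <- ep_loss / max(nb, 1L)
    vtop1 <- wln_eval_top1(theta, vgraphs, config$n_wl_iterations, d)
    log_loss <- c(log_loss, ep_loss); log_top1 <- c(log_top1, vtop1)
    if (vtop1 > best_top1 + 1e-12) { best_top1 <- vtop1; best_theta <- theta }
    if (tracker$update(-ep_loss, vtop1)) break
  }
  structure(
    list(theta = best_theta, config = config, d_in = d_in,
         log = data.frame(epoch = seq_along(log_loss), loss = log_loss,
                          valid_top1 = log_top1),
         best_valid_top1 = best_top1),
    class = "wln_model"
  )
}

#' @export
print.wln_model <- function(x, ...) {
  cat("WLN SOM model:", x$config$hidden_width, "hidden,",
      x$config$n_wl_iterations, "WL iteration(s),",
      nrow(x$log), "epochs trained; best validation top-1 =",
      round(x$best_valid_top1, 3), "\n")
  invisible(x)
}

#' Local WL atom features
#'
#' Runs only the iterative neighbor/bond merging of the network and returns
#' the per-atom local feature matrix. Exposed for diagnostics and
#' permutation/locality testing.
#'
#' @param model a `wln_model` (or a bare parameter list via `theta =`).
#' @param mol substrate molecule.
#' @param n_iter override the configured iteration count.
#' @param include_sugar include the co-reactant atoms.
#' @export
wl_update <- function(model, mol, n_iter = NULL, include_sugar = FALSE) {
  mg <- resolve_graph(mol)
  g <- wln_reaction_graph(mg, include_sugar = include_sugar)
  r <- if (is.null(n_iter)) model$config$n_wl_iterations else as.integer(n_iter)
  if (r < 1L) stop_ugtsom("bad_config", "n_iter must be >= 1")
  nn_tape()
  p <- nn_wrap_params(model$theta)
  de <- directed_edges(g$edges, g$E)
  h <- wln_local_forward(p, nd_const(g$X), de, g$n, r)
  .nn$tape <- NULL
  nd_val(h)
}

#' Global attention context vectors
#'
#' Computes, for every atom of the reactant system, attention weights over
#' all reactant atoms and the resulting context vector (a convex combination
#' of value projections).
#'
#' @param model a `wln_model`.
#' @param local per-atom local feature matrix (from [wl_update()]).
#' @return list with `context` (matrix) and `weights` (row-stochastic
#'   attention matrix).
#' @export
global_attention <- function(model, local) {
  stopifnot(is.matrix(local), nrow(local) >= 1L)
  nn_tape()
  p <- nn_wrap_params(model$theta)
  h <- nd_const(local)
  at <- wln_attention_forward(p, h, seq_len(nrow(local)),
                              model$config$hidden_width)
  .nn$tape <- NULL
  list(context = nd_val(at$context), weights = nd_val(at$weights))
}

#' Score and rank candidate glucuronidation sites of a substrate
#'
#' The glucuronosyl co-reactant is appended automatically; each candidate
#' site is scored against the anomeric carbon and sites are returned in
#' descending score order (ties broken by ascending atom index, which is
#' canonical order for molecules parsed by [parse_molecule()]).
#'
#' @param model a trained `wln_model`.
#' @param mol substrate (SMILES, molgraph or molecule_record).
#' @param id identifier carried into the result.
#' @return a `som_prediction`: list with `id`, `ranked_sites` (data.frame
#'   `rank`, `atom_index`, `site_class`, `reactivity_score`) and `reason`
#'   (`"ok"` or `"no potential SOM"`).
#' @export
score_sites <- function(model, mol, id = NULL) {
  mg <- resolve_graph(mol)
  if (is.null(id))
    id <- if (inherits(mol, "molecule_record")) mol$id else mg$smiles
  g <- wln_reaction_graph(mg, include_sugar = TRUE)
  if (length(g$sites) == 0L) {
    return(structure(list(
      id = id,
      ranked_sites = data.frame(rank = integer(0), atom_index = integer(0),
                                site_class = character(0),
                                reactivity_score = numeric(0)),
      reason = "no potential SOM"), class = "som_prediction"))
  }
  ranked <- wln_rank_batch(model$theta, list(g), model$config$n_wl_iterations,
                           model$config$hidden_width)[["1"]]
  ord <- order(-ranked$score, ranked$atom)
  df <- data.frame(
    rank = seq_along(ord),
    atom_index = ranked$atom[ord],
    site_class = g$site_class[match(ranked$atom[ord], g$sites)],
    reactivity_score = ranked$score[ord]
  )
  structure(list(id = id, ranked_sites = df, reason = "ok"),
            class = "som_prediction")
}

#' @export
print.som_prediction <- function(x, ...) {
  cat("SOM prediction for", x$id, "\n")
  if (x$reason != "ok") cat(" ", x$reason, "\n") else print(x$ranked_sites)
  invisible(x)
}
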