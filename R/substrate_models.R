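# Substrate/nonsubstrate classification: dataset splitting, five traditional
# learners over fingerprint/descriptor features, two graph classifiers,
# stratified ten-fold cross-validation, top-model selection by MCC,
# soft-voting consensus enumeration, and y-randomization.

TRADITIONAL_METHODS <- c("RF", "SVM", "LR", "NN", "ET")
GRAPH_METHODS <- c("GCN", "AttentiveFP", "GAT", "Weave", "MPNN")

#' Classifier specification
#'
#' @param method one of RF, SVM, LR, NN, ET (vector features) or GCN,
#'   AttentiveFP (graph features). GAT, Weave and MPNN are recognized names
#'   but deliberately unimplemented placeholders.
#' @param feature a [feature_spec()].
#' @param hyperparams named list overriding method defaults.
#' @param seed integer seed for every stochastic part of fitting.
#' @export
classifier_spec <- function(method, feature, hyperparams = list(),
                            seed = 1L) {
  method <- match.arg(method, c(TRADITIONAL_METHODS, GRAPH_METHODS))
  stopifnot(inherits(feature, "feature_spec"))
  graph_feat <- feature$type == "graph"
  if (method %in% GRAPH_METHODS && !graph_feat)
    stop_ugtsom("bad_spec", method, " requires a graph feature")
  if (method %in% TRADITIONAL_METHODS && graph_feat)
    stop_ugtsom("bad_spec", method, " requires vector features")
  structure(list(method = method, feature = feature,
                 hyperparams = hyperparams, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Feature specification for classifiers
#'
#' @param type `"fingerprint"`, `"descriptors"` or `"graph"`.
#' @param kind fingerprint family (for fingerprints) or graph scheme.
#' @param nbits fingerprint width.
#' @export
feature_spec <- function(type = c("fingerprint", "descriptors", "graph"),
                         kind = "morgan", nbits = 1024L) {
  type <- match.arg(type)
  structure(list(type = type,
                 kind = if (type == "graph") "classifier" else kind,
                 nbits = as.integer(nbits)),
            class = "feature_spec")
}

feature_name <- function(fs, method = NULL) {
  base <- switch(fs$type,
    descriptors = "Descriptor",
    fingerprint = if (fs$kind == "maccs") "MACCS"
                  else paste0(tools::toTitleCase(fs$kind), "_", fs$nbits),
    graph = "Graph")
  if (is.null(method)) base else paste(base, method, sep = "_")
}

#' Build the feature block for a set of molecules
#'
#' @param records list of `molecule_record`s.
#' @param fs a [feature_spec()].
#' @return numeric matrix (fingerprints/descriptors) or list of graphs.
#' @export
build_features <- function(records, fs) {
  stopifnot(inherits(fs, "feature_spec"))
  if (fs$type == "graph")
    return(lapply(records, mol_to_graph, scheme = "classifier"))
  if (fs$type == "descriptors") {
    X <- t(vapply(records, function(r) descriptors(r),
                  descriptors(records[[1]])))
    rownames(X) <- NULL
    return(X)
  }
  nb <- if (fs$kind == "maccs") 166L else fs$nbits
  X <- t(vapply(records, function(r)
    as.numeric(fingerprint(r, fs$kind, fs$nbits)$bits), numeric(nb)))
  colnames(X) <- paste0("bit", seq_len(ncol(X)))
  X
}

# --- dataset splitting -----------------------------------------------------

#' Seeded dataset splitting with optional grouping
#'
#' Randomly assigns records to partitions with the requested fractions.
#' When `grouping` is given, all records sharing a group key land in the
#' same partition (e.g. reactions of the same reactant).
#'
#' @param n number of records (or a list whose length is used).
#' @param fractions numeric vector summing to 1 (e.g. `c(train = .8,
#'   test = .2)`).
#' @param seed integer seed.
#' @param grouping optional vector of group keys, length `n`.
#' @return list of integer index vectors, named like `fractions`.
#' @export
split_dataset <- function(n, fractions, seed = 1L, grouping = NULL) {
  if (is.list(n)) n <- length(n)
  if (abs(sum(fractions) - 1) > 1e-8)
    stop_ugtsom("bad_fractions", "fractions must sum to 1")
  if (is.null(names(fractions)))
    names(fractions) <- paste0("part", seq_along(fractions))
  set.seed(seed)
  targets <- round(n * fractions)
  targets[length(targets)] <- n - sum(targets[-length(targets)])
  if (any(targets < 0)) stop_ugtsom("bad_fractions", "invalid fractions")
  parts <- lapply(targets, function(x) integer(0))
  if (is.null(grouping)) {
    ord <- sample(n)
    at <- 0L
    for (p in seq_along(targets)) {
      parts[[p]] <- sort(ord[at + seq_len(targets[p])])
      at <- at + targets[p]
    }
  } else {
    stopifnot(length(grouping) == n)
    groups <- split(seq_len(n), as.character(grouping))
    if (max(lengths(groups)) > max(targets))
      stop_ugtsom("group_too_large",
                  "a group is larger than the largest partition")
    for (g in sample(names(groups))) {
      deficit <- targets - lengths(parts)
      fit <- which(deficit >= length(groups[[g]]))
      p <- if (length(fit)) fit[which.max(deficit[fit])] else
        which.max(deficit)
      parts[[p]] <- c(parts[[p]], groups[[g]])
    }
    parts <- lapply(parts, sort)
  }
  parts
}

# --- traditional learners --------------------------------------------------

default_hyperparams <- function(method, ncol_x) {
  switch(method,
    RF = list(ntree = 500L),
    ET = list(num.trees = 500L),
    SVM = list(cost = 1, gamma = 1 / max(ncol_x, 1L)),
    LR = list(lambda = 0.01),
    NN = list(size = 8L, decay = 0.1, maxit = 300L),
    list())
}

needs_scaling <- function(method) method %in% c("SVM", "LR", "NN")

#' Train a traditional classifier
#'
#' RF ([randomForest::randomForest]), ET (extremely randomized trees via
#' [ranger::ranger] with the extratrees split rule), SVM with Platt
#' probability calibration ([e1071::svm]), ridge-penalized logistic
#' regression ([glmnet::glmnet]) and a single-hidden-layer neural network
#' ([nnet::nnet]). SVM/LR/NN inputs are standardized with a scaler fit on
#' the training matrix; all fits are seeded and single-threaded.
#'
#' @param spec a [classifier_spec()] with a traditional method.
#' @param X numeric feature matrix.
#' @param y 0/1 labels (both classes required).
#' @return a `trained_model` exposing class-1 probabilities via
#'   [predict_model()].
#' @export
train_traditional <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"),
            spec$method %in% TRADITIONAL_METHODS)
  X <- as.matrix(X); y <- as.integer(y)
  if (nrow(X) != length(y))
    stop_ugtsom("bad_input", "X rows and y length differ")
  if (length(unique(y)) < 2L)
    stop_ugtsom("single_class", "training labels contain a single class")
  hp <- utils::modifyList(default_hyperparams(spec$method, ncol(X)),
                          spec$hyperparams)
  scaler <- NULL
  if (needs_scaling(spec$method)) {
    scaler <- fit_scaler(X)
    X <- apply_scaler(scaler, X)
  } else {
    med <- fit_scaler(X)
    X <- as.matrix(X)
    for (j in seq_len(ncol(X)))
      X[!is.finite(X[, j]), j] <- med$median[j]
    scaler <- list(impute_only = med)
  }
  if (any(!is.finite(X)))
    stop_ugtsom("bad_input", "non-finite features remain after imputation")
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  set.seed(spec$seed)
  fit <- switch(spec$method,
    RF = randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                                    ntree = hp$ntree),
    ET = ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                        num.trees = hp$num.trees, splitrule = "extratrees",
                        probability = TRUE, num.threads = 1L,
                        seed = spec$seed),
    SVM = e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                     kernel = "radial", cost = hp$cost, gamma = hp$gamma,
                     probability = TRUE, scale = FALSE),
    LR = if (all(apply(X, 2, stats::sd) == 0)) {
      # intercept-only degenerate fit: probability is the class prior
      structure(list(prior = mean(y)), class = "lr_prior")
    } else {
      glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                     lambda = hp$lambda)
    },
    NN = nnet::nnet(x = X, y = y, size = hp$size, decay = hp$decay,
                    maxit = hp$maxit, entropy = TRUE, trace = FALSE,
                    MaxNWts = hp$size * (ncol(X) + 2L) + 1L)
  )
  structure(list(spec = spec, fit = fit, scaler = scaler,
                 hyperparams = hp, n_features = ncol(X),
                 training_manifest = list(
                   n = length(y), class_balance = mean(y),
                   feature = feature_name(spec$feature),
                   seed = spec$seed)),
            class = "trained_model")
}

#' Class-1 probability predictions of a trained model
#' @param model a `trained_model`.
#' @param X feature matrix (or list of graphs for graph models).
#' @export
predict_model <- function(model, X) {
  stopifnot(inherits(model, "trained_model"))
  spec <- model$spec
  if (spec$method %in% GRAPH_METHODS)
    return(predict_graph_model(model, X))
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stop_ugtsom("bad_input", "feature width mismatch")
  if (needs_scaling(spec$method)) {
    X <- apply_scaler(model$scaler, X)
  } else {
    for (j in seq_len(ncol(X)))
      X[!is.finite(X[, j]), j] <- model$scaler$impute_only$median[j]
  }
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  switch(spec$method,
    RF = unname(stats::predict(model$fit, X, type = "prob")[, "1"]),
    ET = unname(stats::predict(model$fit, data = X,
                               num.threads = 1L)$predictions[, "1"]),
    SVM = {
      p <- stats::predict(model$fit, X, probability = TRUE)
      unname(attr(p, "probabilities")[, "1"])
    },
    LR = if (inherits(model$fit, "lr_prior")) rep(model$fit$prior, nrow(X))
         else as.numeric(stats::predict(model$fit, X, type = "response")),
    NN = as.numeric(stats::predict(model$fit, X))
  )
}

# --- graph classifiers -----------------------------------------------------

gcn_param_dims <- function(d_in, d) {
  list(W_in = c(d_in, d), b_in = c(1L, d),
       W_self1 = c(d, d), W_nei1 = c(d, d), b_1 = c(1L, d),
       W_self2 = c(d, d), W_nei2 = c(d, d), b_2 = c(1L, d),
       W_gate = c(d, d), b_gate = c(1L, d),
       W_head = c(2L * d, d), b_head = c(1L, d),
       w_out = c(d, 1L), b_out = c(1L, 1L))
}

afp_param_dims <- function(d_in, d) {
  list(W_in = c(d_in, d), b_in = c(1L, d),
       W_att = c(2L * d, d), b_att = c(1L, d), w_att = c(d, 1L),
       W_val = c(d, d), W_upd = c(d, d), b_upd = c(1L, d),
       W_matt = c(2L * d, d), b_matt = c(1L, d), w_matt = c(d, 1L),
       W_head = c(d, d), b_head = c(1L, d),
       w_out = c(d, 1L), b_out = c(1L, 1L))
}

prepare_graph_batch <- function(graphs) {
  offs <- cumsum(c(0L, vapply(graphs, function(g) nrow(g$node_feats),
                              integer(1))))
  X <- do.call(rbind, lapply(graphs, `[[`, "node_feats"))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(t)
    graphs[[t]]$edges + offs[t]))
  graph_of <- rep(seq_along(graphs),
                  vapply(graphs, function(g) nrow(g$node_feats), integer(1)))
  de <- if (nrow(edges)) list(src = c(edges[, 1], edges[, 2]),
                              dst = c(edges[, 2], edges[, 1]))
        else list(src = integer(0), dst = integer(0))
  deg <- tabulate(de$dst, nbins = nrow(X))
  list(X = X, de = de, graph_of = graph_of, n = nrow(X),
       ngraph = length(graphs), inv_deg = 1 / pmax(deg, 1L),
       inv_size = 1 / tabulate(graph_of, nbins = length(graphs)))
}

gcn_forward <- function(p, b) {
  h <- nd_relu(nd_add(nd_matmul(nd_const(b$X), p$W_in), p$b_in))
  layer <- function(h, Ws, Wn, bias) {
    m <- if (length(b$de$src))
      nd_mul(nd_rowsum_by(nd_rows(h, b$de$src), b$de$dst, b$n),
             nd_const(matrix(b$inv_deg, b$n, ncol(h$val))))
    else nd_scale(h, 0)
    nd_relu(nd_add(nd_add(nd_matmul(h, Ws), nd_matmul(m, Wn)), bias))
  }
  h <- layer(h, p$W_self1, p$W_nei1, p$b_1)
  h <- layer(h, p$W_self2, p$W_nei2, p$b_2)
  gate <- nd_sigmoid(nd_add(nd_matmul(h, p$W_gate), p$b_gate))
  ws <- nd_rowsum_by(nd_mul(gate, h), b$graph_of, b$ngraph)
  mp <- nd_maxpool_by(h, b$graph_of, b$ngraph)
  r <- nd_relu(nd_add(nd_matmul(nd_concat_cols(ws, mp), p$W_head), p$b_head))
  nd_add(nd_matmul(r, p$w_out), p$b_out)
}

afp_forward <- function(p, b, rounds = 2L) {
  h <- nd_relu(nd_add(nd_matmul(nd_const(b$X), p$W_in), p$b_in))
  for (t in seq_len(rounds)) {
    if (length(b$de$src)) {
      pair <- nd_concat_cols(nd_rows(h, b$de$src), nd_rows(h, b$de$dst))
      e <- nd_matmul(nd_relu(nd_add(nd_matmul(pair, p$W_att), p$b_att)),
                     p$w_att)
      a <- nd_softmax_by(e, b$de$dst, b$n)
      msg <- nd_mul(nd_matmul(nd_rows(h, b$de$src), p$W_val),
                    nd_matmul(a, nd_const(matrix(1, 1L, ncol(h$val)))))
      m <- nd_rowsum_by(msg, b$de$dst, b$n)
      h <- nd_relu(nd_add(nd_add(nd_matmul(h, p$W_upd), m), p$b_upd))
    } else {
      h <- nd_relu(nd_add(nd_matmul(h, p$W_upd), p$b_upd))
    }
  }
  # molecule-level attentive readout
  s <- nd_mul(nd_rowsum_by(h, b$graph_of, b$ngraph),
              nd_const(matrix(b$inv_size, b$ngraph, ncol(h$val))))
  for (t in seq_len(rounds)) {
    pair <- nd_concat_cols(nd_rows(s, b$graph_of), h)
    e <- nd_matmul(nd_relu(nd_add(nd_matmul(pair, p$W_matt), p$b_matt)),
                   p$w_matt)
    a <- nd_softmax_by(e, b$graph_of, b$ngraph)
    pooled <- nd_rowsum_by(
      nd_mul(h, nd_matmul(a, nd_const(matrix(1, 1L, ncol(h$val))))),
      b$graph_of, b$ngraph)
    s <- nd_tanh(nd_add(nd_matmul(s, p$W_upd), pooled))
  }
  r <- nd_relu(nd_add(nd_matmul(s, p$W_head), p$b_head))
  nd_add(nd_matmul(r, p$w_out), p$b_out)
}

#' Train a graph neural classifier
#'
#' `GCN`: two rounds of mean-aggregated message passing, readout by
#' concatenated gated weighted-sum and max-pooling, feed-forward head.
#' `AttentiveFP`: attention at the atom level (neighbor attention during
#' message passing) followed by attention at the molecule level (attentive
#' readout rounds), in the spirit of attentive fingerprint networks.
#' Training minimizes binary cross-entropy with logits under Adam and stops
#' early per `policy`, monitoring training loss and validation AUC on an
#' internal seeded 10% split.
#'
#' @param spec a [classifier_spec()] with method GCN or AttentiveFP.
#' @param graphs list of graphs from [mol_to_graph()].
#' @param y 0/1 labels.
#' @param policy an [early_stop_policy()].
#' @return a `trained_model`.
#' @export
train_graph_classifier <- function(spec, graphs, y,
                                   policy = early_stop_policy()) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (spec$method %in% c("GAT", "Weave", "MPNN"))
    stop_ugtsom("not_implemented", spec$method,
                " is a registered but unimplemented classifier")
  stopifnot(spec$method %in% c("GCN", "AttentiveFP"),
            length(graphs) == length(y), length(graphs) > 0L)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop_ugtsom("single_class", "training labels contain a single class")
  hp <- utils::modifyList(list(hidden = 32L, lr = 0.005), spec$hyperparams)
  d_in <- ncol(graphs[[1]]$node_feats)
  dims <- if (spec$method == "GCN") gcn_param_dims(d_in, hp$hidden)
          else afp_param_dims(d_in, hp$hidden)
  theta <- nn_init_params(dims, seed = spec$seed)
  fwd <- if (spec$method == "GCN") gcn_forward else afp_forward

  set.seed(spec$seed)
  nv <- max(2L, floor(0.1 * length(y)))
  vi <- c(sample(which(y == 1), max(1L, round(nv * mean(y)))),
          sample(which(y == 0), max(1L, nv - round(nv * mean(y)))))
  ti <- setdiff(seq_along(y), vi)
  bt <- prepare_graph_batch(graphs[ti])
  bv <- prepare_graph_batch(graphs[vi])
  yt <- matrix(y[ti], ncol = 1L); yv <- y[vi]

  st <- adam_init(theta)
  tracker <- early_stop_tracker(policy)
  best_theta <- theta; best_auc <- -Inf
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    valid_auc = numeric(0))
  for (epoch in seq_len(policy$max_epochs)) {
    nn_tape()
    p <- nn_wrap_params(theta)
    loss <- nd_bce_logits(fwd(p, bt), yt)
    if (!is.finite(nd_val(loss)))
      stop_ugtsom("divergence", "non-finite training loss at epoch ", epoch)
    nn_backward(loss)
    g <- nn_collect_grads(p)
    .nn$tape <- NULL
    upd <- adam_step(theta, g, st, lr = hp$lr)
    theta <- upd$theta; st <- upd$state
    nn_tape()
    vprob <- as.numeric(nd_val(fwd(nn_wrap_params(theta), bv)))
    .nn$tape <- NULL
    vauc <- tryCatch(auc_score(vprob, yv), ugtsom_error = function(e) 0.5)
    log <- rbind(log, data.frame(epoch = epoch, loss = nd_val(loss),
                                 valid_auc = vauc))
    if (vauc > best_auc + 1e-12) { best_auc <- vauc; best_theta <- theta }
    if (tracker$update(-nd_val(loss), vauc)) break
  }
  structure(list(spec = spec, fit = list(theta = best_theta, dims = dims),
                 hyperparams = hp, n_features = d_in, log = log,
                 training_manifest = list(n = length(y),
                                          class_balance = mean(y),
                                          feature = "Graph",
                                          seed = spec$seed)),
            class = "trained_model")
}

predict_graph_model <- function(model, graphs) {
  hp <- model$hyperparams
  fwd <- if (model$spec$method == "GCN") gcn_forward else afp_forward
  b <- prepare_graph_batch(graphs)
  nn_tape()
  z <- as.numeric(nd_val(fwd(nn_wrap_params(model$fit$theta), b)))
  .nn$tape <- NULL
  1 / (1 + exp(-z))
}

#' @export
print.trained_model <- function(x, ...) {
  cat("trained", x$spec$method, "on",
    x$training_manifest$feature, "features (n =",
    x$training_manifest$n, ")\n")
  invisible(x)
}

# --- cross-validation ------------------------------------------------------

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Folds are stratified by class and seeded. Metrics (ACC/SE/SP/MCC at the
#' 0.5 threshold, rank AUC) are reported per fold and on the concatenated
#' out-of-fold predictions.
#'
#' @param spec a [classifier_spec()].
#' @param features matrix (traditional) or list of graphs (graph methods).
#' @param y 0/1 labels.
#' @param k folds (default 10).
#' @param seed fold-assignment seed.
#' @return list with `per_fold`, `summary` (means), `oof` (out-of-fold
#'   probabilities/labels) and `model_name`.
#' @export
cross_validate <- function(spec, features, y, k = 10L, seed = 1L) {
  stopifnot(k >= 2L)
  y <- as.integer(y)
  n <- length(y)
  fold <- stratified_folds(y, k, seed)
  oof <- rep(NA_real_, n)
  rows <- list()
  is_graph <- spec$method %in% GRAPH_METHODS
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    model <- if (is_graph)
      train_graph_classifier(spec, features[tr], y[tr])
    else
      train_traditional(spec, features[tr, , drop = FALSE], y[tr])
    prob <- predict_model(model, if (is_graph) features[te]
                          else features[te, , drop = FALSE])
    oof[te] <- prob
    m <- confusion_metrics(count_confusion(as.integer(prob >= 0.5), y[te]))
    rows[[f]] <- data.frame(
      fold = f, ACC = m$ACC, SE = m$SE, SP = m$SP, MCC = m$MCC,
      AUC = tryCatch(auc_score(prob, y[te]), ugtsom_error = function(e) NA_real_))
  }
  per_fold <- do.call(rbind, rows)
  mo <- confusion_metrics(count_confusion(as.integer(oof >= 0.5), y))
  summary <- data.frame(
    model = feature_name(spec$feature, spec$method),
    ACC = mo$ACC, SE = mo$SE, SP = mo$SP, MCC = mo$MCC,
    AUC = auc_score(oof, y))
  list(per_fold = per_fold, summary = summary,
       oof = list(prob = oof, truth = y, fold = fold),
       model_name = summary$model, spec = spec)
}

#' Rank cross-validated models and keep the best
#'
#' Descending MCC, ties broken by AUC then by model name (stable).
#'
#' @param cv_summaries data.frame with columns `model`, `MCC`, `AUC` (for
#'   instance `rbind` of `cross_validate()$summary` rows).
#' @param n how many to keep.
#' @export
select_top_models <- function(cv_summaries, n = 10L) {
  stopifnot(is.data.frame(cv_summaries),
            all(c("model", "MCC", "AUC") %in% names(cv_summaries)))
  if (n > nrow(cv_summaries))
    stop_ugtsom("bad_input", "asked for top ", n, " of ",
                nrow(cv_summaries), " models")
  ord <- order(-cv_summaries$MCC, -cv_summaries$AUC, cv_summaries$model)
  cv_summaries[ord[seq_len(n)], , drop = FALSE]
}

#' Enumerate soft-voting consensus subsets
#'
#' All subsets of `min_size`..m member models, in deterministic order (by
#' subset size, then combination order). With the default `min_size = 2`,
#' m models yield `2^m - m - 1` proper committees (1013 for m = 10). With
#' `min_size = 1` the degenerate single-member committees are included and
#' the total is `2^m - 1` (1023 for m = 10), which is the headline count
#' reported for ten-model consensus enumeration in the UGT literature; a
#' single-member soft vote is identical to that member model.
#'
#' @param top_models character vector of member model names (2 to 10).
#' @param min_size smallest committee size (1 or 2).
#' @return list of `consensus_spec`s (each: `members`, `threshold`).
#' @export
enumerate_consensus <- function(top_models, min_size = 2L) {
  m <- length(top_models)
  if (m < 2L || m > 10L)
    stop_ugtsom("bad_input", "need between 2 and 10 top models, got ", m)
  if (anyDuplicated(top_models))
    stop_ugtsom("bad_input", "member models must be distinct")
  if (!min_size %in% c(1L, 2L))
    stop_ugtsom("bad_input", "min_size must be 1 or 2")
  out <- list()
  for (size in min_size:m) {
    cmb <- utils::combn(top_models, size, simplify = FALSE)
    for (s in cmb)
      out[[length(out) + 1L]] <- structure(
        list(members = s, threshold = 0.5), class = "consensus_spec")
  }
  out
}

#' Soft-voting consensus prediction
#'
#' The consensus probability is the arithmetic mean of the member class-1
#' probabilities; an item is called a substrate when the mean is greater
#' than or equal to 0.5 (boundary inclusive). A missing member prediction is
#' an error: members are never dropped silently.
#'
#' @param consensus a `consensus_spec` from [enumerate_consensus()].
#' @param member_probs matrix of member probabilities (columns named by
#'   model) or named vector for a single item.
#' @return list with `probability` and `label` vectors.
#' @export
soft_vote <- function(consensus, member_probs) {
  stopifnot(inherits(consensus, "consensus_spec"))
  if (is.vector(member_probs)) member_probs <- t(as.matrix(member_probs))
  missing <- setdiff(consensus$members, colnames(member_probs))
  if (length(missing))
    stop_ugtsom("missing_member", "no predictions for member(s): ",
                paste(missing, collapse = ", "))
  P <- member_probs[, consensus$members, drop = FALSE]
  if (any(!is.finite(P)))
    stop_ugtsom("missing_member", "non-finite member probability")
  prob <- rowMeans(P)
  list(probability = unname(prob),
       label = as.integer(prob >= consensus$threshold))
}

#' y-Randomization check
#'
#' Re-runs cross-validation with shuffled labels `n_rounds` times and
#' reports the distribution of shuffled-label MCCs against the true-label
#' MCC, including the empirical quantile of the true value.
#'
#' @inheritParams cross_validate
#' @param n_rounds label permutations (>= 1).
#' @export
y_randomization <- function(spec, features, y, n_rounds = 20L, k = 10L,
                            seed = 1L) {
  stopifnot(n_rounds >= 1L)
  true_mcc <- cross_validate(spec, features, y, k = k, seed = seed)$summary$MCC
  shuffled <- numeric(n_rounds)
  for (r in seq_len(n_rounds)) {
    set.seed(seed + 1000L + r)
    ys <- sample(y)
    shuffled[r] <- cross_validate(spec, features, ys, k = k,
                                  seed = seed + r)$summary$MCC
  }
  list(true_mcc = true_mcc, shuffled_mcc = shuffled,
       quantile = mean(shuffled < true_mcc))
}
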