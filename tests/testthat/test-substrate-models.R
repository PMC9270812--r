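# Splitting, traditional and graph classifiers, cross-validation,
# consensus enumeration and soft voting.

test_that("split_dataset is seeded, exact and honors grouping", {
  p1 <- split_dataset(10L, c(train = 0.8, test = 0.2), seed = 5)
  p2 <- split_dataset(10L, c(train = 0.8, test = 0.2), seed = 5)
  expect_identical(p1, p2)
  expect_length(p1$train, 8L)
  expect_length(p1$test, 2L)
  expect_setequal(c(p1$train, p1$test), 1:10)

  # grouped records never straddle partitions
  grp <- c("a", "a", "b", "b", "c", "c", "d", "d", "e", "e")
  for (seed in 1:5) {
    p <- split_dataset(10L, c(0.8, 0.2), seed = seed, grouping = grp)
    for (g in unique(grp)) {
      members <- which(grp == g)
      expect_true(all(members %in% p[[1]]) || all(members %in% p[[2]]))
    }
  }
  expect_ugtsom_error(split_dataset(10L, c(0.5, 0.6)), "bad_fractions")
  expect_ugtsom_error(
    split_dataset(10L, c(0.9, 0.1), grouping = rep("g", 10L)),
    "group_too_large")
})

sep_toy <- function() {
  set.seed(10)
  X <- rbind(matrix(rnorm(40, mean = 3), 10), matrix(rnorm(40, mean = -3), 10))
  colnames(X) <- paste0("x", 1:4)
  list(X = X, y = rep(c(1L, 0L), each = 10))
}

test_that("tree ensembles separate a linearly separable toy set perfectly", {
  d <- sep_toy()
  for (meth in c("RF", "ET")) {
    sp <- classifier_spec(meth, feature_spec("descriptors"), seed = 2)
    m <- train_traditional(sp, d$X, d$y)
    pred <- as.integer(predict_model(m, d$X) >= 0.5)
    expect_equal(pred, d$y, info = meth)
  }
})

test_that("logistic regression on constant features returns the class prior", {
  X <- matrix(1, 30, 3)
  y <- c(rep(1L, 21), rep(0L, 9))
  sp <- classifier_spec("LR", feature_spec("descriptors"), seed = 2)
  m <- train_traditional(sp, X, y)
  expect_equal(mean(predict_model(m, X)), 0.7, tolerance = 0.02)
})

test_that("refitting with the same seed reproduces predictions exactly", {
  d <- sep_toy()
  for (meth in c("RF", "ET", "SVM", "NN")) {
    sp <- classifier_spec(meth, feature_spec("descriptors"), seed = 7)
    p1 <- predict_model(train_traditional(sp, d$X, d$y), d$X)
    p2 <- predict_model(train_traditional(sp, d$X, d$y), d$X)
    expect_identical(p1, p2, info = meth)
  }
})

test_that("degenerate training inputs are rejected", {
  d <- sep_toy()
  sp <- classifier_spec("RF", feature_spec("descriptors"))
  expect_ugtsom_error(train_traditional(sp, d$X, rep(1L, 20)), "single_class")
  expect_ugtsom_error(train_traditional(sp, d$X[1:5, ], d$y), "bad_input")
  expect_ugtsom_error(
    classifier_spec("GCN", feature_spec("descriptors")), "bad_spec")
  expect_ugtsom_error(
    classifier_spec("RF", feature_spec("graph")), "bad_spec")
})

test_that("unimplemented graph variants raise rather than alias GCN", {
  gs <- lapply(list("CCO", "CCN", "CCC", "c1ccccc1"), mol_to_graph)
  for (meth in c("GAT", "Weave", "MPNN")) {
    sp <- classifier_spec(meth, feature_spec("graph"))
    expect_ugtsom_error(
      train_graph_classifier(sp, gs, c(1L, 0L, 1L, 0L)), "not_implemented")
  }
})

test_that("cross-validation partitions every sample exactly once", {
  recs <- fx_molecules(60L)
  y <- vapply(recs, `[[`, integer(1), "label")
  X <- build_features(recs, feature_spec("fingerprint", "maccs"))
  sp <- classifier_spec("RF", feature_spec("fingerprint", "maccs"), seed = 3)
  cv <- cross_validate(sp, X, y, k = 5, seed = 3)
  expect_equal(sort(table(cv$oof$fold)), sort(table(rep(1:5, 12))))
  expect_false(anyNA(cv$oof$prob))
  expect_equal(nrow(cv$per_fold), 5L)
  # stratification keeps both classes in every fold
  for (f in 1:5) expect_equal(length(unique(y[cv$oof$fold == f])), 2L)
})

test_that("coin-flip features yield chance-level cross-validated AUC", {
  set.seed(11)
  X <- matrix(rnorm(200 * 10), 200)
  y <- rep(c(0L, 1L), 100)
  sp <- classifier_spec("LR", feature_spec("descriptors"), seed = 4)
  cv <- cross_validate(sp, X, y, k = 5, seed = 4)
  expect_lt(abs(cv$summary$AUC - 0.5), 0.12)
})

test_that("model selection sorts by MCC with AUC then name tie-breaks", {
  df <- data.frame(model = c("a", "b", "c"), MCC = c(0.9, 0.5, 0.7),
                   AUC = c(0.9, 0.8, 0.95))
  top <- select_top_models(df, 2)
  expect_equal(top$model, c("a", "c"))
  df2 <- data.frame(model = c("b", "a"), MCC = c(0.5, 0.5), AUC = c(0.9, 0.95))
  expect_equal(select_top_models(df2, 2)$model, c("a", "b"))
  df3 <- data.frame(model = c("b", "a"), MCC = 0.5, AUC = 0.9)
  expect_equal(select_top_models(df3, 2)$model, c("a", "b"))
  expect_equal(select_top_models(df, 3)$model, c("a", "c", "b"))
  expect_ugtsom_error(select_top_models(df, 4), "bad_input")
})

test_that("consensus enumeration counts follow the subset algebra", {
  expect_length(enumerate_consensus(c("a", "b")), 1L)
  expect_length(enumerate_consensus(c("a", "b", "c")), 4L)
  for (m in 2:10)
    expect_length(enumerate_consensus(paste0("m", 1:m)), 2^m - m - 1)
  # including the degenerate single-member committees: 2^m - 1
  expect_length(enumerate_consensus(paste0("m", 1:10), min_size = 1L),
                1023L)
  expect_ugtsom_error(enumerate_consensus("a"), "bad_input")
  expect_ugtsom_error(enumerate_consensus(c("a", "a")), "bad_input")
})

test_that("soft voting averages probabilities with an inclusive boundary", {
  cs <- enumerate_consensus(c("a", "b"))[[1]]
  P <- matrix(c(0.6, 0.4), 1, dimnames = list(NULL, c("a", "b")))
  sv <- soft_vote(cs, P)
  expect_equal(sv$probability, 0.5)
  expect_equal(sv$label, 1L)            # >= 0.5 is a substrate call
  expect_equal(soft_vote(cs, c(a = 0, b = 0))$label, 0L)

  # consensus probability is bounded by member min/max
  set.seed(5)
  P3 <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  cs3 <- structure(list(members = c("a", "b", "c"), threshold = 0.5),
                   class = "consensus_spec")
  sv3 <- soft_vote(cs3, P3)
  expect_true(all(sv3$probability >= apply(P3, 1, min) - 1e-12))
  expect_true(all(sv3$probability <= apply(P3, 1, max) + 1e-12))

  # identical members: consensus == single model; duplicate agreement is idempotent
  P2 <- matrix(c(0.8, 0.8), 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(soft_vote(cs, P2)$probability, 0.8)
  expect_ugtsom_error(soft_vote(cs3, P), "missing_member")
})

test_that("graph classifiers learn the planted rule and stop by the cap", {
  recs <- fx_molecules(120L)
  y <- vapply(recs, `[[`, integer(1), "label")
  gs <- build_features(recs, feature_spec("graph"))
  ho <- split_dataset(length(y), c(train = .75, test = .25), seed = 8)
  for (meth in c("GCN", "AttentiveFP")) {
    sp <- classifier_spec(meth, feature_spec("graph"), seed = 5)
    m <- train_graph_classifier(sp, gs[ho$train], y[ho$train],
                                early_stop_policy(max_epochs = 60))
    expect_lte(nrow(m$log), 60L)
    auc <- auc_score(predict_model(m, gs[ho$test]), y[ho$test])
    expect_gt(auc, 0.9)
    p <- predict_model(m, gs[ho$test])
    expect_true(all(p >= 0 & p <= 1))
  }
})
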