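# Classification metrics, rank AUC, top-k accuracy, report assembly.

test_that("confusion metrics match the defining formulas on edge cases", {
  m <- confusion_metrics(confusion_counts(5, 0, 5, 0))
  expect_equal(m, list(ACC = 1, SE = 1, SP = 1, MCC = 1))
  m2 <- confusion_metrics(confusion_counts(0, 5, 0, 5))
  expect_equal(m2$ACC, 0)
  expect_equal(m2$MCC, -1)
  m3 <- confusion_metrics(confusion_counts(3, 1, 1, 0))
  expect_equal(m3$ACC, 0.8)
  expect_equal(m3$MCC, (3 * 1 - 1 * 0) / sqrt(4 * 3 * 2 * 1))
  # zero-denominator convention
  expect_equal(confusion_metrics(confusion_counts(5, 0, 0, 0))$MCC, 0)
  expect_error(confusion_counts(0, 0, 0, 0))
})

test_that("ACC is the prevalence-weighted mix of SE and SP", {
  set.seed(1)
  for (i in 1:50) {
    cc <- confusion_counts(tp = sample(0:20, 1) + 1, fp = sample(0:20, 1),
                           tn = sample(0:20, 1) + 1, fn = sample(0:20, 1))
    m <- confusion_metrics(cc)
    n <- cc$tp + cc$fp + cc$tn + cc$fn
    prev <- (cc$tp + cc$fn) / n
    expect_equal(m$ACC, prev * m$SE + (1 - prev) * m$SP)
    expect_true(m$MCC >= -1 && m$MCC <= 1)
  }
})

test_that("rank AUC handles separation, ties and symmetry", {
  expect_equal(auc_score(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(auc_score(rep(1, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  set.seed(2)
  s <- rnorm(40); y <- rbinom(40, 1, 0.5)
  if (length(unique(y)) == 2) {
    expect_equal(auc_score(s, y) + auc_score(-s, y), 1)
    # cross-check against an independent implementation
    expect_equal(auc_score(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
  }
  expect_ugtsom_error(auc_score(1:3, c(1, 1, 1)), "single_class")
})

fake_pred <- function(atoms, scores, classes = NULL) {
  ord <- order(-scores, atoms)
  structure(list(id = "x", ranked_sites = data.frame(
    rank = seq_along(ord), atom_index = atoms[ord],
    site_class = if (is.null(classes)) NA_character_ else classes[ord],
    reactivity_score = scores[ord]), reason = "ok"),
    class = "som_prediction")
}

test_that("top-k accuracy reproduces hand-computed worked examples", {
  p1 <- fake_pred(c(3, 7), c(2, 1))
  expect_equal(topk_accuracy(list(p1), list(3L), 1), 1)
  # two substrates, true sites ranked 1 and 2
  p2 <- fake_pred(c(4, 9), c(5, 9))       # true site 4 ranks second
  expect_equal(topk_accuracy(list(p1, p2), list(3L, 4L), 1), 0.5)
  expect_equal(topk_accuracy(list(p1, p2), list(3L, 4L), 2), 1.0)
  # a true SOM missing from the candidate ranking counts as incorrect
  expect_equal(topk_accuracy(list(p1), list(99L), 5), 0)
  expect_error(topk_accuracy(list(p1), list(3L), 0))
})

test_that("top-k is non-decreasing in k and exact at the candidate count", {
  set.seed(3)
  preds <- list(); truths <- list()
  for (i in 1:30) {
    atoms <- sample(20, 4)
    preds[[i]] <- fake_pred(atoms, rnorm(4))
    truths[[i]] <- sample(atoms, 1)
  }
  accs <- vapply(1:4, function(k) topk_accuracy(preds, truths, k), numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_equal(accs[4], 1)
})

test_that("random scores on four-site substrates give top-1 near 1/4", {
  set.seed(4)
  preds <- list(); truths <- list()
  for (i in 1:200) {
    atoms <- 1:4
    preds[[i]] <- fake_pred(atoms, rnorm(4))
    truths[[i]] <- sample(atoms, 1)
  }
  a1 <- topk_accuracy(preds, truths, 1)
  expect_lt(abs(a1 - 0.25), 3 * sqrt(0.25 * 0.75 / 200))
})

test_that("per-class top-k respects class membership and absence", {
  p <- fake_pred(c(1, 5), c(2, 1), classes = c("ArOH", "Nitrogen"))
  tr <- data.frame(atom_index = 1L, site_class = "ArOH")
  tab <- per_class_topk(list(p), list(tr))
  expect_equal(tab$top_1[tab$site_class == "ArOH"], 1)
  expect_true(is.na(tab$top_1[tab$site_class == "COOH"]))  # absent, not 0
  # single-class data: per-class equals global
  expect_equal(tab$top_1[tab$site_class == "ArOH"],
               topk_accuracy(list(p), list(tr), 1))
})

test_that("evaluation reports are complete and deterministic", {
  cls <- list(perfect = list(pred = c(1, 1, 0, 0), prob = c(.9, .8, .1, .2),
                             truth = c(1, 1, 0, 0)))
  som <- list(wln = list(
    predictions = list(fake_pred(c(2, 6), c(3, 1), c("ArOH", "AlOH"))),
    truths = list(data.frame(atom_index = 2L, site_class = "ArOH"))))
  rep1 <- evaluation_report(cls, som)
  expect_identical(names(rep1$classification),
                   c("Model", "ACC", "SP", "SE", "AUC", "MCC"))
  expect_true(all(rep1$classification[1, -1] == 1))
  expect_equal(rep1$som$top_1, 1)
  rep2 <- evaluation_report(cls, som)
  expect_identical(rep1, rep2)
  tmp <- withr::local_tempdir()
  write_report(rep1, file.path(tmp, "rep"))
  expect_true(file.exists(file.path(tmp, "rep.json")))
  expect_identical(readLines(file.path(tmp, "rep.json")),
                   {write_report(rep1, file.path(tmp, "rep2"))
                    readLines(file.path(tmp, "rep2.json"))})
})
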