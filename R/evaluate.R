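# Classification and ranking metrics, and report assembly.

#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integers.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fp + tn + fn == 0)
    stop_ugtsom("bad_counts", "all confusion counts are zero")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

#' Count a binary prediction against labels
#' @param pred,truth 0/1 vectors of equal length.
#' @export
count_confusion <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  confusion_counts(tp = sum(pred == 1 & truth == 1),
                   fp = sum(pred == 1 & truth == 0),
                   tn = sum(pred == 0 & truth == 0),
                   fn = sum(pred == 0 & truth == 1))
}

#' Accuracy, sensitivity, specificity and Matthews correlation
#'
#' ACC = (TP+TN)/n, SE = TP/(TP+FN), SP = TN/(TN+FP), and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' When any MCC denominator factor is zero the coefficient is defined as 0
#' (the usual convention for degenerate tables); SE/SP are `NaN` when their
#' class is absent.
#'
#' @param counts a [confusion_counts()].
#' @return named list with `ACC`, `SE`, `SP`, `MCC`.
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  acc <- (tp + tn) / n
  se <- if (tp + fn > 0) tp / (tp + fn) else NaN
  sp <- if (tn + fp > 0) tn / (tn + fp) else NaN
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
  list(ACC = acc, SE = se, SP = sp, MCC = mcc)
}

#' Area under the ROC curve (rank statistic)
#'
#' Computed as the Mann-Whitney U statistic: the probability that a random
#' positive scores above a random negative, ties counting one half. This is
#' equivalent to trapezoidal ROC integration and robust to ties.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels 0/1 labels; both classes must be present.
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop_ugtsom("single_class", "AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# normalize a truth entry to a data.frame(atom_index, site_class)
as_truth_df <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("atom_index" %in% names(x))
    if (!"site_class" %in% names(x)) x$site_class <- NA_character_
    return(x[, c("atom_index", "site_class")])
  }
  data.frame(atom_index = as.integer(x), site_class = NA_character_)
}

#' Top-k accuracy of ranked site predictions
#'
#' A substrate counts as correct when any of its true sites of metabolism
#' appears within the first `k` ranked candidate positions; substrates whose
#' true SOM is missing from the candidate ranking count as incorrect.
#'
#' @param predictions list of `som_prediction`s (one per substrate).
#' @param truths list (same length) of true SOM atom indices, either integer
#'   vectors or data.frames with `atom_index` (and optionally `site_class`).
#' @param k rank cut-off (>= 1).
#' @export
topk_accuracy <- function(predictions, truths, k) {
  stopifnot(length(predictions) == length(truths), k >= 1)
  ok <- vapply(seq_along(predictions), function(i) {
    rs <- predictions[[i]]$ranked_sites
    tr <- as_truth_df(truths[[i]])$atom_index
    top <- rs$atom_index[rs$rank <= k]
    as.integer(any(tr %in% top))
  }, integer(1))
  mean(ok)
}

#' Per-class top-k accuracy table
#'
#' Restricts [topk_accuracy()] to the substrates whose true SOM carries each
#' class; a substrate with true sites of several classes contributes to each
#' of them. Classes with no substrates are reported as `NA` (absent), not 0.
#'
#' @inheritParams topk_accuracy
#' @param ks rank cut-offs to tabulate.
#' @return data.frame with `site_class`, `n`, and one `top_k` column per k.
#' @export
per_class_topk <- function(predictions, truths, ks = c(1L, 2L, 3L)) {
  truths <- lapply(truths, as_truth_df)
  out <- lapply(SOM_CLASSES, function(cl) {
    sel <- which(vapply(truths, function(t)
      any(t$site_class == cl, na.rm = TRUE), logical(1)))
    row <- data.frame(site_class = cl, n = length(sel))
    for (k in ks) {
      row[[paste0("top_", k)]] <- if (length(sel) == 0L) NA_real_ else
        topk_accuracy(predictions[sel],
                      lapply(truths[sel], function(t)
                        t[t$site_class == cl, , drop = FALSE]), k)
    }
    row
  })
  do.call(rbind, out)
}

#' Assemble an evaluation report
#'
#' Collects per-model classification rows (ACC/SP/SE/AUC/MCC) and optional
#' SOM-model ranking rows (top-1/2/3, site-level AUC and MCC) into one
#' machine-readable structure; individual metric failures are recorded per
#' cell rather than aborting the report.
#'
#' @param classification named list: each element a list with `pred` (0/1),
#'   `prob` (scores) and `truth` (0/1).
#' @param som named list: each element a list with `predictions`, `truths`
#'   (see [topk_accuracy()]).
#' @return an `evaluation_report`: list of data.frames `classification`
#'   and `som`.
#' @export
evaluation_report <- function(classification = list(), som = list()) {
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  cls <- lapply(names(classification), function(nm) {
    x <- classification[[nm]]
    m <- safe(confusion_metrics(count_confusion(x$pred, x$truth)))
    data.frame(Model = nm,
               ACC = safe(m$ACC), SP = safe(m$SP), SE = safe(m$SE),
               AUC = safe(auc_score(x$prob, x$truth)), MCC = safe(m$MCC))
  })
  soms <- lapply(names(som), function(nm) {
    x <- som[[nm]]
    # site-level binary labels: every ranked candidate scored against truth
    site_scores <- numeric(0); site_labels <- integer(0)
    for (i in seq_along(x$predictions)) {
      rs <- x$predictions[[i]]$ranked_sites
      tr <- as_truth_df(x$truths[[i]])$atom_index
      site_scores <- c(site_scores, rs$reactivity_score)
      site_labels <- c(site_labels, as.integer(rs$atom_index %in% tr))
    }
    data.frame(Model = nm,
               top_1 = safe(topk_accuracy(x$predictions, x$truths, 1L)),
               top_2 = safe(topk_accuracy(x$predictions, x$truths, 2L)),
               top_3 = safe(topk_accuracy(x$predictions, x$truths, 3L)),
               AUC = safe(auc_score(site_scores, site_labels)),
               MCC = safe(confusion_metrics(count_confusion(
                 as.integer(site_scores >= 0), site_labels))$MCC))
  })
  structure(list(classification = do.call(rbind, cls),
                 som = do.call(rbind, soms)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  if (!is.null(x$classification)) {
    cat("Substrate classification\n")
    print(x$classification, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$som)) {
    cat("SOM ranking\n")
    print(x$som, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write an evaluation report as JSON and TSV
#' @param report an [evaluation_report()].
#' @param path_prefix files `<prefix>.json`, `<prefix>_classification.tsv`,
#'   `<prefix>_som.tsv` are written.
#' @export
write_report <- function(report, path_prefix) {
  jsonlite::write_json(unclass(report), paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(report$classification))
    utils::write.table(report$classification,
                       paste0(path_prefix, "_classification.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$som))
    utils::write.table(report$som, paste0(path_prefix, "_som.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
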