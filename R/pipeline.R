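# Two-stage gated prediction workflow: a soft-voting substrate consensus
# feeds the WLN site-of-metabolism ranker; molecules called nonsubstrates
# are gated out of SOM prediction (with an explicit reason, never silence).

#' Derive a stage seed from the run seed
#'
#' One global seed fans out to per-stage seeds (stage name hashed), so
#' stages can be rerun independently yet reproducibly.
#'
#' @param seed integer run seed.
#' @param stage stage name.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((abs(as.numeric(seed)) * 31 +
                hash_seq(utf8ToInt(stage))) %% .Machine$integer.max)
}

#' Default classifier roster for the substrate consensus
#'
#' Five traditional methods on MACCS keys and on the physicochemical
#' descriptor block (ten models), mirroring the feature/method families that
#' dominate cross-validated rankings on UGT substrate data.
#'
#' @param seed base seed; each spec derives its own.
#' @export
default_roster <- function(seed = 1L) {
  specs <- list()
  for (ft in list(feature_spec("fingerprint", "maccs"),
                  feature_spec("descriptors"))) {
    for (m in TRADITIONAL_METHODS) {
      sp <- classifier_spec(m, ft,
                            seed = derive_seed(seed, paste0(m, ft$type)))
      specs[[feature_name(ft, m)]] <- sp
    }
  }
  specs
}

#' Fit a soft-voting substrate consensus
#'
#' Cross-validates every roster model, ranks by MCC (ties by AUC), keeps the
#' `top_n` best, refits them on the full training set and returns the bundle
#' used by [predict_substrate()] and [run_pipeline()].
#'
#' @param records training `molecule_record`s with 0/1 labels.
#' @param roster named list of [classifier_spec()]s (default
#'   [default_roster()]).
#' @param k cross-validation folds.
#' @param top_n consensus size.
#' @param seed fold seed.
#' @return a `substrate_consensus`: members (trained models), consensus
#'   spec, CV table.
#' @export
fit_substrate_consensus <- function(records, roster = NULL, k = 10L,
                                    top_n = 5L, seed = 1L) {
  y <- vapply(records, `[[`, integer(1), "label")
  if (anyNA(y)) stop_ugtsom("bad_input", "all records need 0/1 labels")
  if (is.null(roster)) roster <- default_roster(seed)
  feats <- list()
  cv_rows <- list()
  for (nm in names(roster)) {
    sp <- roster[[nm]]
    fkey <- feature_name(sp$feature)
    if (is.null(feats[[fkey]])) feats[[fkey]] <- build_features(records, sp$feature)
    cv <- cross_validate(sp, feats[[fkey]], y, k = k,
                         seed = derive_seed(seed, "cv"))
    cv_rows[[nm]] <- cv$summary
  }
  cv_table <- do.call(rbind, cv_rows)
  top <- select_top_models(cv_table, n = min(top_n, nrow(cv_table)))
  members <- list()
  for (nm in top$model) {
    sp <- roster[[nm]]
    fkey <- feature_name(sp$feature)
    members[[nm]] <- if (sp$method %in% GRAPH_METHODS)
      train_graph_classifier(sp, feats[[fkey]], y)
    else train_traditional(sp, feats[[fkey]], y)
  }
  structure(list(
    members = members,
    consensus = structure(list(members = names(members), threshold = 0.5),
                          class = "consensus_spec"),
    cv_table = cv_table),
    class = "substrate_consensus")
}

#' @export
print.substrate_consensus <- function(x, ...) {
  cat("substrate consensus of", length(x$members), "models:\n ",
      paste(names(x$members), collapse = ", "), "\n")
  invisible(x)
}

member_probabilities <- function(consensus, records) {
  feats <- list()
  P <- matrix(NA_real_, length(records), length(consensus$members),
              dimnames = list(NULL, names(consensus$members)))
  for (nm in names(consensus$members)) {
    model <- consensus$members[[nm]]
    fkey <- feature_name(model$spec$feature)
    if (is.null(feats[[fkey]]))
      feats[[fkey]] <- build_features(records, model$spec$feature)
    P[, nm] <- predict_model(model, feats[[fkey]])
  }
  P
}

#' Predict substrate probability via the consensus
#'
#' @param consensus a [fit_substrate_consensus()] bundle.
#' @param records list of `molecule_record`s.
#' @return data.frame `id`, `probability` (mean member probability),
#'   `label` (1 iff probability >= 0.5).
#' @export
predict_substrate <- function(consensus, records) {
  P <- member_probabilities(consensus, records)
  sv <- soft_vote(consensus$consensus, P)
  data.frame(id = vapply(records, `[[`, character(1), "id"),
             probability = sv$probability, label = sv$label,
             stringsAsFactors = FALSE)
}

#' Run the gated two-stage prediction pipeline
#'
#' Stage 1 scores every molecule with the substrate consensus; stage 2 ranks
#' candidate glucuronidation sites with the WLN, but only for predicted
#' substrates when gating is on (a molecule is not worth SOM prediction if
#' it is not a UGT substrate). Gated molecules and molecules without
#' candidate sites receive explicit reason strings.
#'
#' @param records list of `molecule_record`s.
#' @param substrate_model a `substrate_consensus` (or `NULL` to skip gating
#'   and stage 1 entirely).
#' @param som_model a trained `wln_model`.
#' @param gate_som_by_substrate gate stage 2 on the stage-1 label.
#' @param out_dir optional directory; writes `classification.tsv` and
#'   `som_ranks.tsv`.
#' @return list with `classification` (data.frame) and `som` (long
#'   data.frame: id, rank, atom_index, site_class, reactivity_score,
#'   reason).
#' @export
run_pipeline <- function(records, substrate_model = NULL, som_model,
                         gate_som_by_substrate = TRUE, out_dir = NULL) {
  stopifnot(inherits(som_model, "wln_model"))
  cls <- if (!is.null(substrate_model)) {
    predict_substrate(substrate_model, records)
  } else {
    data.frame(id = vapply(records, `[[`, character(1), "id"),
               probability = NA_real_, label = 1L, stringsAsFactors = FALSE)
  }
  som_rows <- list()
  for (i in seq_along(records)) {
    rid <- cls$id[i]
    if (gate_som_by_substrate && !is.null(substrate_model) &&
        cls$label[i] == 0L) {
      som_rows[[i]] <- data.frame(id = rid, rank = NA_integer_,
                                  atom_index = NA_integer_,
                                  site_class = NA_character_,
                                  reactivity_score = NA_real_,
                                  reason = "not predicted: nonsubstrate",
                                  stringsAsFactors = FALSE)
      next
    }
    pred <- score_sites(som_model, records[[i]], id = rid)
    som_rows[[i]] <- if (pred$reason != "ok") {
      data.frame(id = rid, rank = NA_integer_, atom_index = NA_integer_,
                 site_class = NA_character_, reactivity_score = NA_real_,
                 reason = pred$reason, stringsAsFactors = FALSE)
    } else {
      cbind(id = rid, pred$ranked_sites, reason = "ok",
            stringsAsFactors = FALSE)
    }
  }
  som <- do.call(rbind, som_rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(cls, file.path(out_dir, "classification.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(som, file.path(out_dir, "som_ranks.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(classification = cls, som = som)
}
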