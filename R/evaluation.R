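#' Ranking AUC of a score table against a positive set
#'
#' The probability that a uniformly chosen positive drug outscores a
#' uniformly chosen negative one, with ties counted as half
#' (the Mann-Whitney convention), computed from average ranks.
#'
#' @param scores A `ddcm_scores` data frame (or any data frame with
#'   `drug_id` and `score`).
#' @param positives Character vector of positive drug IDs.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, positives) {
  lab <- scores$drug_id %in% positives
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0 || n_neg == 0)
    stop("auc_score: need at least one positive and one negative drug")
  r <- rank(scores$score, ties.method = "average")
  (sum(r[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Stratified (within-stratum pairs) Mann-Whitney AUC: per-stratum AUCs
# combined with weights n_pos * n_neg, i.e. the probability that a random
# positive outranks a random negative *of the same stratum*. Correlation
# scores are only comparable within one disease, so cross-disease score
# comparisons are never made.
stratified_auc <- function(auc, n_pos, n_neg) {
  w <- n_pos * n_neg
  ok <- !is.na(auc) & w > 0
  if (!any(ok)) return(NA_real_)
  sum(auc[ok] * w[ok]) / sum(w[ok])
}

#' Recovery report against planted truth
#'
#' Measures how well per-disease score tables (and, optionally, final
#' potential-drug sets) recover held-out true associations. Known (training)
#' positives are excluded from every ranking-based metric so the report
#' never rewards memorization of the training labels.
#'
#' @param score_tables Named list of `ddcm_scores` tables keyed by disease.
#' @param known Data frame of training associations (disease_id, drug_id).
#' @param holdout Data frame of held-out true associations.
#' @param k Top-k cut for `recovery_at_k`.
#' @param ptdr Optional named list of potential-drug ID vectors per disease.
#' @details Every drug that appears as a training positive for any disease
#'   is excluded from the ranking metrics of every disease, not just its
#'   own: the fitted model carries each training drug's identity through
#'   its self-similarity column, so trained drugs rank systematically high
#'   and would otherwise contaminate both the positive and the negative
#'   pool. Ranking metrics therefore measure recovery among drugs the model
#'   has never seen labeled.
#' @return A `ddcm_eval` list: `per_disease` data frame (auc,
#'   recovery_at_k, n_pos, n_neg per disease), `pooled_auc` (within-disease
#'   positive/negative pairs pooled over diseases; correlation scores are
#'   not comparable across diseases, so no cross-disease comparison enters),
#'   `recovery_at_k`, and -- when `ptdr` is given -- `ptdr_recall` and
#'   `ptdr_precision` against the holdout.
#' @export
recovery_report <- function(score_tables, known, holdout, k = 50L,
                            ptdr = NULL) {
  ids <- names(score_tables)
  bad <- setdiff(unique(holdout$disease_id), ids)
  if (length(bad))
    stop("recovery_report: no score table for disease(s): ",
         paste(bad, collapse = ", "))
  trained_drugs <- unique(known$drug_id)
  rows <- lapply(ids, function(d) {
    st <- score_tables[[d]]
    st <- st[!st$drug_id %in% trained_drugs, , drop = FALSE]
    pos <- intersect(holdout$drug_id[holdout$disease_id == d], st$drug_id)
    n_pos <- length(pos); n_neg <- nrow(st) - n_pos
    auc <- if (n_pos > 0 && n_neg > 0) auc_score(st, pos) else NA_real_
    rec <- if (n_pos > 0) {
      ord <- order(-st$score, st$drug_id)
      mean(pos %in% st$drug_id[head(ord, k)])
    } else NA_real_
    data.frame(disease_id = d, auc = auc, recovery_at_k = rec,
               n_pos = n_pos, n_neg = n_neg, stringsAsFactors = FALSE)
  })
  per_disease <- do.call(rbind, rows)
  out <- list(per_disease = per_disease,
              pooled_auc = stratified_auc(per_disease$auc, per_disease$n_pos,
                                          per_disease$n_neg),
              recovery_at_k = if (all(is.na(per_disease$recovery_at_k)))
                NA_real_ else mean(per_disease$recovery_at_k, na.rm = TRUE),
              n_pos = sum(per_disease$n_pos),
              n_neg = sum(per_disease$n_neg))
  if (!is.null(ptdr)) {
    hold_key <- association_key(holdout$disease_id, holdout$drug_id)
    pred_key <- unlist(lapply(names(ptdr), function(d)
      association_key(d, setdiff(ptdr[[d]], trained_drugs))))
    out$ptdr_recall <- if (length(hold_key)) mean(hold_key %in% pred_key) else NA_real_
    out$ptdr_precision <- if (length(pred_key)) mean(pred_key %in% hold_key) else NA_real_
  }
  class(out) <- "ddcm_eval"
  out
}

#' @export
print.ddcm_eval <- function(x, ...) {
  cat("ddcm_eval: pooled AUC ", format(x$pooled_auc, digits = 4),
      " over ", x$n_pos, " held-out positives / ", x$n_neg, " negatives\n",
      sep = "")
  if (!is.null(x$ptdr_recall))
    cat("  PtDr recall ", format(x$ptdr_recall, digits = 3),
        ", precision ", format(x$ptdr_precision, digits = 3), "\n", sep = "")
  invisible(x)
}
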