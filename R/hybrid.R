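#' Feature row for one disease-drug pair
#'
#' A pair's feature vector is the concatenation of its drug's combined
#' similarity to every drug (in fixed drug-ID order) followed by its
#' disease's combined similarity to every disease (in fixed disease-ID
#' order), so the row length is always R + D.
#'
#' @param disease_id,drug_id Entity IDs.
#' @param drug_sim,disease_sim Combined `ddcm_similarity` objects.
#' @return Named numeric vector of length `R + D`; names are
#'   `drug:<id>` then `disease:<id>`.
#' @export
pair_features <- function(disease_id, drug_id, drug_sim, disease_sim) {
  if (!drug_id %in% drug_sim$ids)
    stop("pair_features: unknown drug ID: ", drug_id)
  if (!disease_id %in% disease_sim$ids)
    stop("pair_features: unknown disease ID: ", disease_id)
  v <- c(drug_sim$values[drug_id, ], disease_sim$values[disease_id, ])
  names(v) <- c(paste0("drug:", drug_sim$ids), paste0("disease:", disease_sim$ids))
  v
}

hybrid_colnames <- function(drug_sim, disease_sim) {
  c(paste0("drug:", drug_sim$ids), paste0("disease:", disease_sim$ids))
}

#' Build the labeled hybrid training matrix
#'
#' Rows are disease-drug pairs: every known (label 1) association plus
#' negative (label 0) pairs drawn from the unobserved combinations. Columns
#' are all drugs followed by all diseases; entry (p, c) is the combined
#' similarity of the row's drug (or disease) to the column entity.
#'
#' @param dataset A `ddcm_dataset` with a non-empty association table.
#' @param drug_sim,disease_sim Combined similarity matrices covering all
#'   entities of the dataset.
#' @param negative_policy `"all"` to use every non-known pair, or
#'   `"matched:<ratio>"` to sample ratio-times-n_known negatives uniformly
#'   without replacement (default `"matched:1"`).
#' @param seed Integer seed controlling negative sampling; the row order is
#'   deterministic given the seed.
#' @return A `ddcm_hybrid` object: `X` (matrix), `labels` (0/1 vector),
#'   `pairs` (data frame of disease_id, drug_id), and the column layout.
#' @export
build_training_matrix <- function(dataset, drug_sim, disease_sim,
                                  negative_policy = "matched:1", seed = 1L) {
  known <- dataset$associations
  if (!nrow(known)) stop("build_training_matrix: dataset has no known associations")
  if (!all(dataset$drug_ids %in% drug_sim$ids) ||
      !all(dataset$disease_ids %in% disease_sim$ids))
    stop("build_training_matrix: similarity matrices do not cover all entities")

  known <- known[order(known$disease_id, known$drug_id), , drop = FALSE]
  known_key <- association_key(known$disease_id, known$drug_id)

  all_pairs <- expand.grid(drug_id = dataset$drug_ids,
                           disease_id = dataset$disease_ids,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  all_key <- association_key(all_pairs$disease_id, all_pairs$drug_id)
  neg_pool <- all_pairs[!all_key %in% known_key, , drop = FALSE]

  if (identical(negative_policy, "all")) {
    negs <- neg_pool
  } else if (grepl("^matched:", negative_policy)) {
    ratio <- suppressWarnings(as.numeric(sub("^matched:", "", negative_policy)))
    if (!is.finite(ratio) || ratio < 0)
      stop("build_training_matrix: bad negative_policy: ", negative_policy)
    n_neg <- min(nrow(neg_pool), round(ratio * nrow(known)))
    idx <- with_seed(derive_seed(seed, 101L), sample.int(nrow(neg_pool), n_neg))
    negs <- neg_pool[sort(idx), , drop = FALSE]
  } else {
    stop("build_training_matrix: unknown negative_policy: ", negative_policy)
  }
  negs <- negs[order(negs$disease_id, negs$drug_id), , drop = FALSE]

  pairs <- data.frame(
    disease_id = c(known$disease_id, negs$disease_id),
    drug_id = c(known$drug_id, negs$drug_id),
    stringsAsFactors = FALSE
  )
  labels <- c(rep(1, nrow(known)), rep(0, nrow(negs)))
  X <- hybrid_rows(pairs, drug_sim, disease_sim)
  structure(list(X = X, labels = labels, pairs = pairs,
                 drug_ids = drug_sim$ids, disease_ids = disease_sim$ids,
                 negative_policy = negative_policy, seed = seed),
            class = "ddcm_hybrid")
}

# Assemble feature rows for a pair table by block lookup (fast path of
# pair_features over many rows).
hybrid_rows <- function(pairs, drug_sim, disease_sim) {
  X <- cbind(drug_sim$values[pairs$drug_id, , drop = FALSE],
             disease_sim$values[pairs$disease_id, , drop = FALSE])
  dimnames(X) <- list(NULL, hybrid_colnames(drug_sim, disease_sim))
  X
}

#' Build an unlabeled query matrix for one disease
#'
#' One feature row per candidate drug, with the same column layout as the
#' training matrix, so one fitted model scores every pair.
#'
#' @param disease_id Query disease.
#' @param candidate_drugs Character vector of drug IDs (may repeat).
#' @param drug_sim,disease_sim Combined similarity matrices.
#' @return A `ddcm_hybrid` with `labels = NULL`.
#' @export
build_query_matrix <- function(disease_id, candidate_drugs, drug_sim, disease_sim) {
  if (!length(candidate_drugs))
    stop("build_query_matrix: empty candidate drug list")
  unknown <- setdiff(candidate_drugs, drug_sim$ids)
  if (length(unknown))
    stop("build_query_matrix: unknown drug ID(s): ",
         paste(head(unknown, 5), collapse = ", "))
  if (!disease_id %in% disease_sim$ids)
    stop("build_query_matrix: unknown disease ID: ", disease_id)
  pairs <- data.frame(disease_id = disease_id, drug_id = candidate_drugs,
                      stringsAsFactors = FALSE)
  X <- hybrid_rows(pairs, drug_sim, disease_sim)
  structure(list(X = X, labels = NULL, pairs = pairs,
                 drug_ids = drug_sim$ids, disease_ids = disease_sim$ids),
            class = "ddcm_hybrid")
}

#' @export
print.ddcm_hybrid <- function(x, ...) {
  cat("ddcm_hybrid:", nrow(x$X), "pair rows x", ncol(x$X), "columns (",
      length(x$drug_ids), "drugs +", length(x$disease_ids), "diseases )\n")
  if (!is.null(x$labels))
    cat("  labels:", sum(x$labels == 1), "known /", sum(x$labels == 0), "negative\n")
  invisible(x)
}
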