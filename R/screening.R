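#' Screening configuration
#'
#' Bundles the tunable parameters of the stepwise screening pipeline with
#' their standard defaults: top-50 candidate cut, perturbation regimes
#' removing 1, 2 and 5 diseases, M randomizations per regime, 95% stability
#' retention, eps = 0.1, C = 1.
#'
#' @param k Candidate-list size (top-k by correlation score).
#' @param M Number of randomizations per perturbation regime (>= 2).
#' @param regimes Integer vector of regime sizes (diseases removed per run).
#' @param quantile_keep Fraction of ranked stability scores retained.
#' @param epsilon,cost SVR parameters.
#' @param negative_policy Passed to [build_training_matrix()].
#' @param stability_variant `"sd"` (1 minus sample standard deviation, the
#'   default) or `"variance"` (1 minus sample variance) for Eq.-style
#'   stability scores.
#' @param seed Master seed; all pipeline randomness derives from it.
#' @return A list of class `ddcm_config`.
#' @export
screen_config <- function(k = 50L, M = 10L, regimes = c(1L, 2L, 5L),
                          quantile_keep = 0.95, epsilon = 0.1, cost = 1.0,
                          negative_policy = "matched:1",
                          stability_variant = c("sd", "variance"),
                          seed = 42L) {
  stability_variant <- match.arg(stability_variant)
  stopifnot(k >= 1, M >= 2, quantile_keep > 0, quantile_keep <= 1,
            epsilon >= 0, cost > 0, all(regimes >= 1))
  structure(list(k = as.integer(k), M = as.integer(M),
                 regimes = as.integer(regimes),
                 quantile_keep = quantile_keep, epsilon = epsilon, cost = cost,
                 negative_policy = negative_policy,
                 stability_variant = stability_variant,
                 seed = as.integer(seed)),
            class = "ddcm_config")
}

#' Top-k drug candidates for a disease
#'
#' Takes the k highest de-redundant correlation scores; drugs ranked after
#' the k-th are discarded. Ties are broken deterministically by ascending
#' drug ID, so a tie at the boundary keeps the lexicographically smaller ID.
#'
#' @param scores A `ddcm_scores` table from [score_disease()].
#' @param k Cut-off (default 50).
#' @return A `ddcm_candidates` data frame: `rank`, `drug_id`, `score`.
#' @export
top_candidates <- function(scores, k = 50L) {
  if (!nrow(scores)) stop("top_candidates: empty score table")
  ord <- order(-scores$score, scores$drug_id)
  keep <- ord[seq_len(min(k, nrow(scores)))]
  out <- data.frame(rank = seq_along(keep),
                    drug_id = scores$drug_id[keep],
                    score = scores$score[keep],
                    stringsAsFactors = FALSE)
  attr(out, "disease_id") <- scores$disease_id[1]
  class(out) <- c("ddcm_candidates", "data.frame")
  out
}

#' Stability score of an occurrence-indicator vector
#'
#' One indicator per randomization run: 1 if the drug appeared in that
#' run's top-k candidate list, else 0. The stability score is 1 minus the
#' sample spread (standard deviation by default, with divisor M - 1) of the
#' indicators; a drug present (or absent) in every run scores exactly 1.
#'
#' @param indicators 0/1 vector of length M >= 2.
#' @param variant `"sd"` or `"variance"`.
#' @return A number (1 for zero spread, decreasing with volatility).
#' @export
#' @examples
#' stability_score(c(1, 1, 1, 1))  # 1
#' stability_score(c(1, 1, 0, 0))  # 1 - sqrt(1/3)
stability_score <- function(indicators, variant = c("sd", "variance")) {
  variant <- match.arg(variant)
  if (length(indicators) < 2L) stop("stability_score: need M >= 2 indicators")
  if (!all(indicators %in% c(0, 1)))
    stop("stability_score: indicators must be 0/1")
  v <- sum((indicators - mean(indicators))^2) / (length(indicators) - 1)
  1 - if (variant == "sd") sqrt(v) else v
}

#' Run one regime of randomized perturbations
#'
#' For each of M runs, removes j uniformly sampled diseases (never the
#' query disease) from the training matrix -- dropping every training row,
#' known or negative, whose disease was removed, while keeping the
#' similarity feature columns fixed -- refits the SVR, rescores the query
#' disease, and records the top-k candidate set.
#'
#' @param train Full `ddcm_hybrid` training matrix.
#' @param query_disease Query disease ID (never removed).
#' @param j Number of diseases removed per run.
#' @param M Number of runs (>= 2).
#' @param seed Regime seed; run i uses a substream derived from it.
#' @param drug_sim,disease_sim Combined similarity matrices.
#' @param config A `ddcm_config` (epsilon, cost, k).
#' @return List of M runs, each with `removed_diseases` and `top` (the
#'   top-k drug IDs) plus `scores`.
#' @export
run_perturbations <- function(train, query_disease, j, M, seed,
                              drug_sim, disease_sim, config = screen_config()) {
  others <- setdiff(disease_sim$ids, query_disease)
  if (j >= length(others))
    stop("run_perturbations: j = ", j, " must be < number of diseases - 1")
  if (M < 2L) stop("run_perturbations: M must be >= 2")
  q <- build_query_matrix(query_disease, drug_sim$ids, drug_sim, disease_sim)
  lapply(seq_len(M), function(i) {
    removed <- with_seed(derive_seed(seed, i), sample(others, j))
    keep <- !train$pairs$disease_id %in% removed
    model <- fit_svr(train$X[keep, , drop = FALSE], train$labels[keep],
                     epsilon = config$epsilon, cost = config$cost)
    s <- predict(model, q)
    agg <- tapply(s, q$pairs$drug_id, max)
    st <- data.frame(disease_id = query_disease, drug_id = names(agg),
                     score = as.numeric(agg), stringsAsFactors = FALSE)
    class(st) <- c("ddcm_scores", "data.frame")
    top <- top_candidates(st, config$k)
    list(removed_diseases = sort(removed), top = top$drug_id, scores = st)
  })
}

# Retain the top `frac` of named scores (descending); ties at the cut kept.
keep_top_fraction <- function(scores, frac) {
  if (!length(scores)) return(character(0))
  n_keep <- ceiling(frac * length(scores))
  thr <- sort(scores, decreasing = TRUE)[n_keep]
  names(scores)[scores >= thr]
}

#' Per-drug stability table across all perturbation regimes
#'
#' Tabulates, for every drug that appears in the unperturbed candidate list
#' or in any perturbation run, its occurrence indicators, per-regime
#' stability scores Sj, regime eligibility (a drug absent from all M runs
#' of a regime also has zero spread, but is ineligible for that regime's
#' stable set), and the total stability score over M' = 3M + 1 indicators
#' (all regimes' runs plus the unperturbed prediction).
#'
#' @param drc `ddcm_candidates` from the unperturbed model.
#' @param runs Named list of regime run lists (names are regime sizes as
#'   character, e.g. `"1"`, `"2"`, `"5"`), as from [run_perturbations()].
#' @param config A `ddcm_config`.
#' @return A `ddcm_stability` data frame with one row per drug.
#' @export
stability_table <- function(drc, runs, config = screen_config()) {
  regimes <- as.character(config$regimes)
  if (!all(regimes %in% names(runs)))
    stop("stability_table: missing regime run(s): ",
         paste(setdiff(regimes, names(runs)), collapse = ", "))
  M <- length(runs[[regimes[1]]])
  drugs <- sort(unique(c(drc$drug_id,
                         unlist(lapply(runs, function(rr)
                           unlist(lapply(rr, `[[`, "top"))), use.names = FALSE))))
  tab <- data.frame(drug_id = drugs, stringsAsFactors = FALSE)
  tab$in_DrC <- drugs %in% drc$drug_id
  indicators <- list()
  for (r in regimes) {
    I <- vapply(runs[[r]], function(run) as.numeric(drugs %in% run$top),
                numeric(length(drugs)))
    I <- matrix(I, nrow = length(drugs))
    indicators[[r]] <- I
    tab[[paste0("S", r)]] <-
      apply(I, 1, stability_score, variant = config$stability_variant)
    tab[[paste0("eligible", r)]] <- rowSums(I) > 0
  }
  all_ind <- cbind(do.call(cbind, indicators), as.numeric(tab$in_DrC))
  stopifnot(ncol(all_ind) == length(regimes) * M + 1L)
  tab$SSDrC <- apply(all_ind, 1, stability_score,
                     variant = config$stability_variant)
  attr(tab, "indicators") <- indicators
  attr(tab, "M") <- M
  class(tab) <- c("ddcm_stability", "data.frame")
  tab
}

#' Stable drug candidates (regime intersection)
#'
#' For each regime j, the stable set DrSj holds the regime-eligible drugs
#' whose Sj lies in the top `quantile_keep` fraction of ranked scores (the
#' bottom 5% discarded by default; ties at the cut retained). The stable
#' candidate set is the intersection of all regime stable sets with the
#' unperturbed candidate list: SDrC = DrS1 n DrS2 n DrS5 n DrC.
#'
#' @param stability A `ddcm_stability` table.
#' @param drc `ddcm_candidates`.
#' @param config A `ddcm_config`.
#' @return Character vector of stable candidate drug IDs (sorted), with the
#'   per-regime stable sets attached as attribute `"DrSj"`.
#' @export
stable_candidates <- function(stability, drc, config = screen_config()) {
  drsj <- list()
  for (r in as.character(config$regimes)) {
    scol <- paste0("S", r); ecol <- paste0("eligible", r)
    if (!scol %in% names(stability))
      stop("stable_candidates: stability table lacks regime ", r)
    elig <- stability[[ecol]]
    s <- stats::setNames(stability[[scol]][elig], stability$drug_id[elig])
    drsj[[r]] <- keep_top_fraction(s, config$quantile_keep)
  }
  out <- Reduce(intersect, c(drsj, list(drc$drug_id)))
  out <- sort(out)
  attr(out, "DrSj") <- drsj
  out
}

#' Potential therapeutic drugs (total-stability cut)
#'
#' Among the stable candidates, keeps those whose total stability score
#' SSDrC -- computed over all M' = 3M + 1 occurrence indicators -- lies in
#' the top `quantile_keep` fraction. A drug present in every run has
#' SSDrC = 1 and is always retained.
#'
#' @param stability A `ddcm_stability` table.
#' @param sdrc Stable candidate set from [stable_candidates()].
#' @param config A `ddcm_config`.
#' @return Sorted character vector of potential therapeutic drug IDs.
#' @export
potential_drugs <- function(stability, sdrc, config = screen_config()) {
  if (!length(sdrc)) {
    warning("potential_drugs: empty stable candidate set")
    return(character(0))
  }
  idx <- match(sdrc, stability$drug_id)
  if (anyNA(idx)) stop("potential_drugs: stable candidates missing from table")
  s <- stats::setNames(stability$SSDrC[idx], sdrc)
  sort(keep_top_fraction(s, config$quantile_keep))
}

#' Full stepwise screening for one disease
#'
#' Executes the pipeline end to end: similarity computation, hybrid
#' training matrix, SVR fit, de-redundant scoring, top-k candidates (DrC),
#' randomized perturbation in every regime, per-regime stability scores and
#' stable sets, their intersection (SDrC), total stability, and the final
#' potential therapeutic drug set (PtDr). The containment chain
#' PtDr subset-of SDrC subset-of DrC holds by construction.
#'
#' @param dataset A `ddcm_dataset`.
#' @param query_disease Disease ID to screen.
#' @param config A `ddcm_config`.
#' @param sims Optional precomputed [dataset_similarities()] result.
#' @return A `ddcm_screen` object holding every intermediate.
#' @export
screen_disease <- function(dataset, query_disease, config = screen_config(),
                           sims = NULL) {
  if (!query_disease %in% dataset$disease_ids)
    stop("screen_disease: unknown disease: ", query_disease)
  sims <- sims %||% dataset_similarities(dataset)
  train <- build_training_matrix(dataset, sims$drug, sims$disease,
                                 negative_policy = config$negative_policy,
                                 seed = config$seed)
  model <- fit_svr(train, epsilon = config$epsilon, cost = config$cost)
  scores <- score_disease(model, query_disease, sims$drug, sims$disease)
  drc <- top_candidates(scores, config$k)
  runs <- list()
  for (j in config$regimes) {
    runs[[as.character(j)]] <- run_perturbations(
      train, query_disease, j, config$M,
      seed = derive_seed(config$seed, 1000L + j),
      drug_sim = sims$drug, disease_sim = sims$disease, config = config)
  }
  stability <- stability_table(drc, runs, config)
  sdrc <- stable_candidates(stability, drc, config)
  ptdr <- potential_drugs(stability, sdrc, config)
  stability$in_SDrC <- stability$drug_id %in% sdrc
  stability$in_PtDr <- stability$drug_id %in% ptdr
  for (r in names(attr(sdrc, "DrSj")))
    stability[[paste0("in_DrS", r)]] <-
      stability$drug_id %in% attr(sdrc, "DrSj")[[r]]
  structure(list(disease_id = query_disease, config = config,
                 model = model, scores = scores, candidates = drc,
                 runs = runs, stability = stability,
                 sdrc = as.character(sdrc), ptdr = ptdr),
            class = "ddcm_screen")
}

#' @export
print.ddcm_screen <- function(x, ...) {
  cat("ddcm_screen for disease ", x$disease_id, ":\n", sep = "")
  cat("  DrC (candidates):        ", nrow(x$candidates), "\n")
  cat("  SDrC (stable candidates):", length(x$sdrc), "\n")
  cat("  PtDr (potential drugs):  ", length(x$ptdr), "\n")
  invisible(x)
}

#' Write screening outputs to a directory
#'
#' Emits `candidates.tsv` (rank, drug, score), `stability.tsv` (per-drug
#' stability scores and set-membership flags), `ptdr.tsv`, and a
#' `manifest.json` capturing the configuration, so every artifact is
#' reconstructible from the manifest plus the input data.
#'
#' @param result A `ddcm_screen`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(result$candidates, file.path(dir, "candidates.tsv"))
  stab <- result$stability
  attr(stab, "indicators") <- NULL; attr(stab, "M") <- NULL
  num <- vapply(stab, is.numeric, TRUE)
  stab[num] <- lapply(stab[num], function(v) formatC(v, digits = 12, format = "g"))
  write_tsv(stab, file.path(dir, "stability.tsv"))
  write_tsv(data.frame(drug_id = result$ptdr, stringsAsFactors = FALSE),
            file.path(dir, "ptdr.tsv"))
  cfg <- unclass(result$config)
  jsonlite::write_json(list(disease_id = result$disease_id, config = cfg,
                            n_candidates = nrow(result$candidates),
                            n_stable = length(result$sdrc),
                            n_potential = length(result$ptdr)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
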