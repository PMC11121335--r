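#' Configuration for the synthetic benchmark generator
#'
#' The generator emulates the statistical structure the screening method
#' assumes: diseases fall into clusters sharing a core pool of pathogenic
#' genes and pathways; each truly therapeutic drug's target set overlaps the
#' genes of the diseases it treats; the association table is only partially
#' observed, with the unobserved remainder held out as recovery truth.
#'
#' Counts may be single integers or `c(min, max)` ranges sampled per entity.
#'
#' @param n_diseases,n_drugs,n_genes,n_pathways Universe sizes.
#' @param n_clusters Number of disease clusters.
#' @param genes_per_disease,pathways_per_disease Membership sizes.
#' @param targets_per_drug,pathways_per_drug Drug membership sizes.
#' @param drugs_per_disease True therapeutic drugs per disease.
#' @param therapeutic_drug_fraction Fraction of drugs eligible to be
#'   therapeutic at all; the rest are background drugs whose targets are
#'   uniform draws from the gene universe. Each therapeutic drug is
#'   assigned to exactly one disease, so held-out associations can only be
#'   recovered through profile similarity, never by memorizing a drug ID
#'   seen with another disease during training.
#' @param within_cluster_gene_overlap,within_cluster_pathway_overlap
#'   Fraction of a disease's memberships drawn from its cluster's core pool.
#' @param therapeutic_target_overlap,therapeutic_pathway_overlap Fraction of
#'   a therapeutic drug's memberships guaranteed to come from each treated
#'   disease's own memberships.
#' @param observed_fraction Fraction of true associations revealed as known.
#' @param noise_feature_rate Fraction of cluster-core draws replaced by
#'   uniform background features, blurring the cluster signal.
#' @param seed Master seed; generation is fully reproducible from it.
#' @return A list of class `ddcm_synth_config`.
#' @export
synthetic_config <- function(n_diseases = 20L, n_drugs = 100L,
                             n_genes = 500L, n_pathways = 120L,
                             n_clusters = 4L,
                             genes_per_disease = c(15L, 30L),
                             pathways_per_disease = c(5L, 10L),
                             targets_per_drug = c(5L, 15L),
                             pathways_per_drug = c(3L, 8L),
                             drugs_per_disease = c(2L, 3L),
                             therapeutic_drug_fraction = 0.6,
                             within_cluster_gene_overlap = 0.6,
                             within_cluster_pathway_overlap = 0.6,
                             therapeutic_target_overlap = 0.6,
                             therapeutic_pathway_overlap = 0.6,
                             observed_fraction = 0.7,
                             noise_feature_rate = 0.2,
                             seed = 1L) {
  cfg <- list(n_diseases = n_diseases, n_drugs = n_drugs, n_genes = n_genes,
              n_pathways = n_pathways, n_clusters = n_clusters,
              genes_per_disease = genes_per_disease,
              pathways_per_disease = pathways_per_disease,
              targets_per_drug = targets_per_drug,
              pathways_per_drug = pathways_per_drug,
              drugs_per_disease = drugs_per_disease,
              therapeutic_drug_fraction = therapeutic_drug_fraction,
              within_cluster_gene_overlap = within_cluster_gene_overlap,
              within_cluster_pathway_overlap = within_cluster_pathway_overlap,
              therapeutic_target_overlap = therapeutic_target_overlap,
              therapeutic_pathway_overlap = therapeutic_pathway_overlap,
              observed_fraction = observed_fraction,
              noise_feature_rate = noise_feature_rate,
              seed = as.integer(seed))
  counts <- cfg[c("n_diseases", "n_drugs", "n_genes", "n_pathways", "n_clusters")]
  if (any(unlist(counts) < 1)) stop("synthetic_config: counts must be positive")
  fracs <- cfg[c("therapeutic_drug_fraction",
                 "within_cluster_gene_overlap", "within_cluster_pathway_overlap",
                 "therapeutic_target_overlap", "therapeutic_pathway_overlap",
                 "observed_fraction", "noise_feature_rate")]
  if (any(unlist(fracs) < 0 | unlist(fracs) > 1))
    stop("synthetic_config: fractions must lie in [0, 1]")
  if (max(genes_per_disease) > n_genes || max(pathways_per_disease) > n_pathways ||
      max(targets_per_drug) > n_genes || max(pathways_per_drug) > n_pathways)
    stop("synthetic_config: membership sizes exceed universe sizes")
  structure(cfg, class = "ddcm_synth_config")
}

draw_count <- function(spec) {
  if (length(spec) == 1L) as.integer(spec)
  else sample(seq.int(spec[1], spec[2]), 1L)
}

pad_ids <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(n), seq_len(n))

#' Generate a synthetic disease-drug dataset with planted truth
#'
#' See [synthetic_config()] for the generative model. The returned object
#' carries the assembled dataset (with only the observed associations), the
#' full true association set, and the held-out remainder used for recovery
#' evaluation. All data are synthetic; IDs follow `D..`/`R..`/`G..`/`P..`
#' conventions for diseases, drugs, genes and pathways.
#'
#' @param config A `ddcm_synth_config`.
#' @return A `ddcm_synth` list: `dataset` (class `ddcm_dataset`), `truth`
#'   and `holdout` data frames, `clusters`, and the `config`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  with_seed(config$seed, generate_synthetic_impl(config))
}

generate_synthetic_impl <- function(cfg) {
  diseases <- pad_ids("D", cfg$n_diseases)
  drugs <- pad_ids("R", cfg$n_drugs)
  genes <- pad_ids("G", cfg$n_genes)
  pathways <- pad_ids("P", cfg$n_pathways)

  clusters <- rep_len(seq_len(cfg$n_clusters), cfg$n_diseases)
  names(clusters) <- diseases

  core_size <- function(universe_n, per_entity)
    min(universe_n, max(per_entity) * 2L)
  gene_cores <- lapply(seq_len(cfg$n_clusters), function(cl)
    sample(genes, core_size(cfg$n_genes, cfg$genes_per_disease)))
  pathway_cores <- lapply(seq_len(cfg$n_clusters), function(cl)
    sample(pathways, core_size(cfg$n_pathways, cfg$pathways_per_disease)))

  # A disease's memberships: a core-pool fraction (thinned by the noise
  # rate) plus uniform background features.
  draw_members <- function(core, universe, n_total, core_frac, noise_rate) {
    n_core <- round(core_frac * (1 - noise_rate) * n_total)
    n_core <- min(n_core, length(core))
    picked <- sample(core, n_core)
    rest <- sample(setdiff(universe, picked), n_total - n_core)
    sort(c(picked, rest))
  }

  disease_genes <- list(); disease_pathways <- list()
  for (d in diseases) {
    cl <- clusters[[d]]
    disease_genes[[d]] <- draw_members(
      gene_cores[[cl]], genes, draw_count(cfg$genes_per_disease),
      cfg$within_cluster_gene_overlap, cfg$noise_feature_rate)
    disease_pathways[[d]] <- draw_members(
      pathway_cores[[cl]], pathways, draw_count(cfg$pathways_per_disease),
      cfg$within_cluster_pathway_overlap, cfg$noise_feature_rate)
  }

  # True therapeutic assignments: a global pool of therapeutic drugs is
  # partitioned over diseases without replacement (one disease per drug).
  n_ther <- max(cfg$n_diseases, round(cfg$therapeutic_drug_fraction * cfg$n_drugs))
  pool <- sample(drugs, n_ther)
  truth <- list()
  for (d in diseases) {
    nd <- draw_count(cfg$drugs_per_disease)
    if (nd > length(pool))
      stop("generate_synthetic: therapeutic drug pool exhausted; raise ",
           "therapeutic_drug_fraction or lower drugs_per_disease")
    truth[[d]] <- sort(pool[seq_len(nd)])
    pool <- pool[-seq_len(nd)]
  }
  treated_by <- split(rep(names(truth), lengths(truth)),
                      unlist(truth, use.names = FALSE))

  drug_genes <- list(); drug_pathways <- list()
  planted <- function(drug, universe, per_drug, overlap, disease_sets) {
    n_total <- draw_count(per_drug)
    sig <- character(0)
    for (d in treated_by[[drug]] %||% character(0)) {
      need <- ceiling(overlap * n_total)
      have <- disease_sets[[d]]
      if (need > length(have))
        stop("generate_synthetic: requested overlap ", overlap,
             " infeasible for drug ", drug, " and disease ", d,
             " (needs ", need, " of ", length(have), " members)")
      sig <- union(sig, sample(have, need))
    }
    n_noise <- max(0L, n_total - length(sig))
    sort(c(sig, sample(setdiff(universe, sig), n_noise)))
  }
  for (r in drugs) {
    drug_genes[[r]] <- planted(r, genes, cfg$targets_per_drug,
                               cfg$therapeutic_target_overlap, disease_genes)
    drug_pathways[[r]] <- planted(r, pathways, cfg$pathways_per_drug,
                                  cfg$therapeutic_pathway_overlap,
                                  disease_pathways)
  }

  truth_df <- data.frame(
    disease_id = rep(names(truth), lengths(truth)),
    drug_id = unlist(truth, use.names = FALSE),
    stringsAsFactors = FALSE)
  truth_df <- truth_df[order(truth_df$disease_id, truth_df$drug_id), ]
  rownames(truth_df) <- NULL
  n_known <- round(cfg$observed_fraction * nrow(truth_df))
  known_idx <- sort(sample.int(nrow(truth_df), n_known))
  known <- truth_df[known_idx, , drop = FALSE]
  holdout <- truth_df[-known_idx, , drop = FALSE]
  rownames(known) <- rownames(holdout) <- NULL
  known$source <- "synthetic"

  dataset <- suppressMessages(assemble_dataset(
    disease_genes, disease_pathways, drug_genes, drug_pathways, known))
  structure(list(dataset = dataset, truth = truth_df, holdout = holdout,
                 clusters = clusters, config = cfg),
            class = "ddcm_synth")
}

#' @export
print.ddcm_synth <- function(x, ...) {
  cat("ddcm_synth:", length(x$dataset$disease_ids), "diseases,",
      length(x$dataset$drug_ids), "drugs;", nrow(x$truth), "true pairs (",
      nrow(x$dataset$associations), "known /", nrow(x$holdout), "held out )\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits exactly the files the data model reads -- four GMT files, the
#' known-association TSV and a `manifest.json` naming them -- plus
#' `truth.tsv` and `holdout.tsv` for evaluation only. The truth files are
#' deliberately not referenced by the manifest, so a pipeline driven by the
#' manifest can never see the held-out answers.
#'
#' @param synth A `ddcm_synth`.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_dataset <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- synth$dataset
  write_gmt(ds$disease_genes, file.path(dir, "disease_genes.gmt"))
  write_gmt(ds$disease_pathways, file.path(dir, "disease_pathways.gmt"))
  write_gmt(ds$drug_genes, file.path(dir, "drug_genes.gmt"))
  write_gmt(ds$drug_pathways, file.path(dir, "drug_pathways.gmt"))
  write_tsv(ds$associations, file.path(dir, "associations.tsv"))
  write_tsv(synth$truth, file.path(dir, "truth.tsv"))
  write_tsv(synth$holdout, file.path(dir, "holdout.tsv"))
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(
    disease_genes = "disease_genes.gmt",
    disease_pathways = "disease_pathways.gmt",
    drug_genes = "drug_genes.gmt",
    drug_pathways = "drug_pathways.gmt",
    associations = "associations.tsv",
    generator = list(seed = synth$config$seed)
  ), manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
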