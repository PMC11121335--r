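#' Binary membership vector for one entity
#'
#' Maps a feature set onto a fixed, ordered feature universe: positions of
#' members are 1, all others 0. The universe order is fixed at dataset
#' assembly (lexicographic), so vectors are bit-reproducible across runs.
#'
#' @param members Character vector of member IDs.
#' @param space Ordered character vector of all feature IDs for this level.
#' @return An integer 0/1 vector of `length(space)`, named by feature ID.
#' @export
#' @examples
#' binary_vector("G2", c("G1", "G2", "G3"))
binary_vector <- function(members, space) {
  unknown <- setdiff(members, space)
  if (length(unknown))
    stop("binary_vector: member(s) not in feature space: ",
         paste(head(unknown, 5), collapse = ", "))
  stats::setNames(as.integer(space %in% members), space)
}

#' Adjusted cosine similarity of two vectors
#'
#' Cosine similarity after centering each vector by its own mean:
#' \deqn{R = \frac{\sum_i (A_i-\bar\alpha)(B_i-\bar\beta)}
#'  {\sqrt{\sum_i (A_i-\bar\alpha)^2}\sqrt{\sum_i (B_i-\bar\beta)^2}}}
#' On binary membership vectors this equals the phi coefficient of the
#' 2x2 membership contingency table.
#'
#' A constant (all-zero or all-one) vector makes a denominator zero; such
#' pairs carry no similarity evidence and return `degenerate_value` (0 by
#' default) rather than NaN. Self-pairs of degenerate entities are handled
#' at the matrix level, where the diagonal is set to 1 by convention.
#'
#' @param a,b Numeric vectors of equal length (>= 2).
#' @param degenerate_value Value returned when either vector is constant.
#' @return A number in \[-1, 1\].
#' @export
#' @examples
#' acs(c(1, 1, 0, 0, 0), c(1, 0, 1, 0, 0))  # 1/6
acs <- function(a, b, degenerate_value = 0) {
  if (length(a) != length(b)) stop("acs: vectors must have equal length")
  if (length(a) < 2L) stop("acs: vectors must have length >= 2")
  ac <- a - mean(a)
  bc <- b - mean(b)
  da <- sqrt(sum(ac * ac))
  db <- sqrt(sum(bc * bc))
  if (da == 0 || db == 0) return(degenerate_value)
  v <- sum(ac * bc) / (da * db)
  min(1, max(-1, v))
}

#' Pairwise adjusted-cosine similarity matrix at one level
#'
#' Computes the full symmetric entity-by-entity ACS matrix for one level
#' (gene or pathway) of one entity kind. Entities whose membership vector is
#' constant at this level (empty set, or full membership) are degenerate:
#' every off-diagonal entry involving them is 0 and they are flagged, while
#' their diagonal is set to 1 by convention.
#'
#' @param sets Named list of member-ID vectors, one per entity (missing
#'   levels represented as empty vectors).
#' @param space Ordered feature universe for this level. May be empty, in
#'   which case every entity is degenerate.
#' @param level Label stored on the result, e.g. `"gene"` or `"pathway"`.
#' @return A `ddcm_similarity` object: list with `ids`, `values` (named
#'   matrix), `level`, and `degenerate` (named logical).
#' @export
level_similarity <- function(sets, space, level = "gene") {
  ids <- names(sets)
  if (length(ids) < 2L) stop("level_similarity: need >= 2 profiles")
  n <- length(ids)
  N <- length(space)
  if (N >= 2L) {
    V <- matrix(0L, nrow = n, ncol = N, dimnames = list(ids, space))
    for (i in seq_len(n)) V[i, ] <- binary_vector(sets[[i]], space)
    rs <- rowSums(V)
    degenerate <- rs == 0L | rs == N
    # centered rows; correlation via cross-products on the non-degenerate block
    Vc <- V - rs / N
    norms <- sqrt(rowSums(Vc * Vc))
    S <- tcrossprod(Vc)
    denom <- outer(norms, norms)
    vals <- matrix(0, n, n, dimnames = list(ids, ids))
    ok <- denom > 0
    vals[ok] <- S[ok] / denom[ok]
    vals[!ok] <- 0
    vals <- pmin(pmax(vals, -1), 1)
  } else {
    degenerate <- rep(TRUE, n)
    vals <- matrix(0, n, n, dimnames = list(ids, ids))
  }
  names(degenerate) <- ids
  # exact symmetry (guard against FP asymmetry from tcrossprod scaling)
  vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
  diag(vals) <- 1
  if (any(degenerate))
    message("level_similarity (", level, "): ", sum(degenerate),
            " degenerate (constant) profile vector(s); pairs involving them scored 0")
  structure(list(ids = ids, values = vals, level = level, degenerate = degenerate),
            class = "ddcm_similarity")
}

#' @export
print.ddcm_similarity <- function(x, ...) {
  cat("ddcm_similarity (", x$level, "): ", length(x$ids), " x ",
      length(x$ids), " entities, ", sum(x$degenerate), " degenerate\n", sep = "")
  invisible(x)
}

#' Combine gene- and pathway-level similarities
#'
#' The final similarity between two entities is the unweighted arithmetic
#' mean of their gene-level and pathway-level adjusted-cosine similarities.
#' When exactly one level is usable for a pair (the other level degenerate
#' or absent for either entity), the single available level's value is used
#' unchanged; when neither level is usable the pair scores 0. The diagonal
#' is always 1.
#'
#' @param gene_sim,pathway_sim `ddcm_similarity` objects over identical IDs
#'   in identical order.
#' @return A `ddcm_similarity` tagged `"combined"`.
#' @export
combined_similarity <- function(gene_sim, pathway_sim) {
  if (!identical(gene_sim$ids, pathway_sim$ids))
    stop("combined_similarity: ID orderings differ between levels")
  ids <- gene_sim$ids
  okg <- !gene_sim$degenerate
  okp <- !pathway_sim$degenerate
  # pair usability: both entities non-degenerate at that level
  Ug <- outer(okg, okg, `&`)
  Up <- outer(okp, okp, `&`)
  num <- gene_sim$values * Ug + pathway_sim$values * Up
  den <- Ug + Up
  vals <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  use <- den > 0
  vals[use] <- num[use] / den[use]
  diag(vals) <- 1
  structure(list(ids = ids, values = vals, level = "combined",
                 degenerate = !(okg | okp)),
            class = "ddcm_similarity")
}

#' Compute combined entity similarities for a dataset
#'
#' Convenience wrapper producing the combined drug-drug and disease-disease
#' similarity matrices the hybrid matrix is built from.
#'
#' @param dataset A `ddcm_dataset`.
#' @return List with `disease` and `drug` combined `ddcm_similarity`
#'   objects, plus the four per-level matrices under `levels`.
#' @export
dataset_similarities <- function(dataset) {
  dg <- level_similarity(dataset$disease_genes, dataset$spaces$disease_gene, "gene")
  dp <- level_similarity(dataset$disease_pathways, dataset$spaces$disease_pathway, "pathway")
  rg <- level_similarity(dataset$drug_genes, dataset$spaces$drug_gene, "gene")
  rp <- level_similarity(dataset$drug_pathways, dataset$spaces$drug_pathway, "pathway")
  list(disease = combined_similarity(dg, dp),
       drug = combined_similarity(rg, rp),
       levels = list(disease_gene = dg, disease_pathway = dp,
                     drug_gene = rg, drug_pathway = rp))
}

#' Write a similarity matrix as TSV
#'
#' ID-indexed square matrix with a header row and an `id` column, for
#' inspection and interchange.
#'
#' @param sim A `ddcm_similarity`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_similarity <- function(sim, path) {
  df <- data.frame(id = sim$ids, sim$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a similarity matrix written by [write_similarity()]
#'
#' @param path TSV path.
#' @param level Level tag to store on the result.
#' @return A `ddcm_similarity` (degeneracy flags are not recoverable from
#'   the file and are set to FALSE).
#' @export
read_similarity <- function(path, level = "combined") {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  ids <- as.character(df$id)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- ids
  structure(list(ids = ids, values = vals, level = level,
                 degenerate = stats::setNames(rep(FALSE, length(ids)), ids)),
            class = "ddcm_similarity")
}
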