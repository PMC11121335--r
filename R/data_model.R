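#' Read a GMT gene-set file
#'
#' Parses the standard tab-delimited GMT format: one set per line, with the
#' set name in the first field, a free-text description in the second, and
#' the member identifiers in the remaining fields. Used here for pathogenic
#' gene sets and disease/drug pathway sets alike.
#'
#' @param path Path to a GMT file.
#' @param kind What the members are, `"gene"` or `"pathway"`. Recorded as an
#'   attribute on the result; parsing is identical for both.
#' @return A named list of character vectors (one per set). Names are set
#'   identifiers; each vector holds the unique member IDs of that set.
#' @details Malformed lines (fewer than three fields, i.e. no members) and
#'   duplicated set names are errors, reported with their line numbers.
#' @export
#' @examples
#' tmp <- tempfile(fileext = ".gmt")
#' writeLines("D1\tna\tG1\tG2", tmp)
#' read_gmt(tmp, "gene")
read_gmt <- function(path, kind = c("gene", "pathway")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 3L)
  if (length(bad)) {
    stop("GMT parse error in ", path, ": line ", bad[1],
         " has ", n_fields[bad[1]], " tab-separated field(s); ",
         "expected set name, description and at least one member")
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("GMT validation error in ", path, ": duplicate set name(s): ",
         paste(unique(dup), collapse = ", "))
  }
  sets <- lapply(fields, function(f) {
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    members
  })
  empty <- which(lengths(sets) == 0L)
  if (length(empty)) {
    stop("GMT parse error in ", path, ": line ", empty[1],
         " (set '", ids[empty[1]], "') has no non-empty members")
  }
  names(sets) <- ids
  attr(sets, "kind") <- kind
  sets
}

#' Write a named list of sets to a GMT file
#'
#' Inverse of [read_gmt()]. Sets with zero members are skipped (GMT cannot
#' represent them); the caller is expected to track such entities separately.
#'
#' @param sets Named list of character vectors.
#' @param path Output file path.
#' @param description Description field written on every line.
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  keep <- lengths(sets) > 0L
  lines <- vapply(which(keep), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a disease-drug association table
#'
#' Reads a tab-delimited file with header columns `disease_id` and `drug_id`
#' (and optionally `source`). Duplicate pairs are dropped with a message.
#'
#' @param path Path to a TSV file.
#' @return A data frame with columns `disease_id`, `drug_id` and `source`
#'   (NA where absent), one row per unique pair.
#' @export
read_associations <- function(path) {
  if (!file.exists(path)) stop("Association file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", quote = "")
  required <- c("disease_id", "drug_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("Association file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!nrow(df)) stop("Association file ", path, " has no rows")
  if (!"source" %in% names(df)) df$source <- NA_character_
  df <- df[, c("disease_id", "drug_id", "source")]
  key <- paste(df$disease_id, df$drug_id, sep = "\r")
  dups <- duplicated(key)
  if (any(dups)) {
    message("read_associations: dropped ", sum(dups), " duplicate pair(s)")
    df <- df[!dups, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Assemble a validated disease-drug dataset
#'
#' Combines per-entity gene and pathway sets with a known-association table
#' into a single dataset object. Feature universes (the fixed, ordered gene
#' and pathway vocabularies used for vectorization) are built as the
#' lexicographically sorted union of observed memberships, separately per
#' entity kind and level, so disease vectors and drug vectors never share a
#' coordinate system.
#'
#' @param disease_genes,disease_pathways Named lists of character vectors
#'   keyed by disease ID (as returned by [read_gmt()]). Either may omit
#'   entities present in the other; such entities are retained and flagged.
#' @param drug_genes,drug_pathways Same, keyed by drug ID.
#' @param associations Data frame from [read_associations()], or NULL.
#' @param lenient If TRUE, associations referencing unknown entities are
#'   dropped with a warning instead of raising an error.
#' @return An object of class `ddcm_dataset`: lists of profiles, the four
#'   feature spaces, sorted entity ID vectors, and the association table.
#' @export
assemble_dataset <- function(disease_genes, disease_pathways,
                             drug_genes, drug_pathways,
                             associations = NULL, lenient = FALSE) {
  if (!length(disease_genes) && !length(disease_pathways))
    stop("No disease profiles supplied")
  if (!length(drug_genes) && !length(drug_pathways))
    stop("No drug profiles supplied")

  norm <- function(x) if (is.null(x)) list() else lapply(x, function(s) sort(unique(as.character(s))))
  disease_genes <- norm(disease_genes); disease_pathways <- norm(disease_pathways)
  drug_genes <- norm(drug_genes); drug_pathways <- norm(drug_pathways)

  disease_ids <- sort(unique(c(names(disease_genes), names(disease_pathways))))
  drug_ids <- sort(unique(c(names(drug_genes), names(drug_pathways))))
  overlap <- intersect(disease_ids, drug_ids)
  if (length(overlap))
    stop("IDs used for both a disease and a drug: ", paste(overlap, collapse = ", "))

  spaces <- list(
    disease_gene    = sort(unique(unlist(disease_genes, use.names = FALSE))),
    disease_pathway = sort(unique(unlist(disease_pathways, use.names = FALSE))),
    drug_gene       = sort(unique(unlist(drug_genes, use.names = FALSE))),
    drug_pathway    = sort(unique(unlist(drug_pathways, use.names = FALSE)))
  )

  fill <- function(sets, ids) {
    out <- stats::setNames(vector("list", length(ids)), ids)
    for (id in ids) out[[id]] <- sets[[id]] %||% character(0)
    out
  }
  disease_genes <- fill(disease_genes, disease_ids)
  disease_pathways <- fill(disease_pathways, disease_ids)
  drug_genes <- fill(drug_genes, drug_ids)
  drug_pathways <- fill(drug_pathways, drug_ids)

  flag_missing <- function(sets, label) {
    miss <- names(sets)[lengths(sets) == 0L]
    if (length(miss))
      message("assemble_dataset: ", length(miss), " entit",
              if (length(miss) == 1) "y" else "ies",
              " lacking the ", label, " level: ",
              paste(head(miss, 5), collapse = ", "),
              if (length(miss) > 5) ", ..." else "")
    miss
  }
  missing_levels <- list(
    disease_gene = flag_missing(disease_genes, "disease gene"),
    disease_pathway = flag_missing(disease_pathways, "disease pathway"),
    drug_gene = flag_missing(drug_genes, "drug gene"),
    drug_pathway = flag_missing(drug_pathways, "drug pathway")
  )

  if (!is.null(associations)) {
    bad_d <- setdiff(associations$disease_id, disease_ids)
    bad_r <- setdiff(associations$drug_id, drug_ids)
    if (length(bad_d) || length(bad_r)) {
      offenders <- c(
        if (length(bad_d)) paste0("diseases: ", paste(bad_d, collapse = ", ")),
        if (length(bad_r)) paste0("drugs: ", paste(bad_r, collapse = ", "))
      )
      if (lenient) {
        drop <- associations$disease_id %in% bad_d | associations$drug_id %in% bad_r
        warning("assemble_dataset: dropping ", sum(drop),
                " association(s) referencing unknown entities (",
                paste(offenders, collapse = "; "), ")")
        associations <- associations[!drop, , drop = FALSE]
      } else {
        stop("Associations reference unknown entities (",
             paste(offenders, collapse = "; "), ")")
      }
    }
    key <- paste(associations$disease_id, associations$drug_id, sep = "\r")
    associations <- associations[!duplicated(key), , drop = FALSE]
    rownames(associations) <- NULL
  } else {
    associations <- data.frame(disease_id = character(0), drug_id = character(0),
                               source = character(0), stringsAsFactors = FALSE)
  }

  structure(list(
    disease_ids = disease_ids, drug_ids = drug_ids,
    disease_genes = disease_genes, disease_pathways = disease_pathways,
    drug_genes = drug_genes, drug_pathways = drug_pathways,
    spaces = spaces, associations = associations,
    missing_levels = missing_levels
  ), class = "ddcm_dataset")
}

#' @export
print.ddcm_dataset <- function(x, ...) {
  cat("ddcm_dataset:", length(x$disease_ids), "diseases,",
      length(x$drug_ids), "drugs,", nrow(x$associations), "known associations\n")
  cat("  feature spaces: disease genes", length(x$spaces$disease_gene),
      "| disease pathways", length(x$spaces$disease_pathway),
      "| drug genes", length(x$spaces$drug_gene),
      "| drug pathways", length(x$spaces$drug_pathway), "\n")
  invisible(x)
}

# Known-pair membership lookup used by the hybrid module.
association_key <- function(disease_id, drug_id) paste(disease_id, drug_id, sep = "\r")

#' Load a dataset from a JSON manifest
#'
#' The manifest names the five input files (four GMT, one association TSV),
#' with paths resolved relative to the manifest's directory.
#'
#' @param path Path to a manifest JSON with entries `disease_genes`,
#'   `disease_pathways`, `drug_genes`, `drug_pathways`, `associations`.
#' @param lenient Passed to [assemble_dataset()].
#' @return A `ddcm_dataset`.
#' @export
read_dataset <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stop("Dataset manifest not found: ", path)
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)
  assemble_dataset(
    disease_genes = read_gmt(resolve(man$disease_genes), "gene"),
    disease_pathways = read_gmt(resolve(man$disease_pathways), "pathway"),
    drug_genes = read_gmt(resolve(man$drug_genes), "gene"),
    drug_pathways = read_gmt(resolve(man$drug_pathways), "pathway"),
    associations = read_associations(resolve(man$associations)),
    lenient = lenient
  )
}
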