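# Internal helpers: seeded RNG scoping and deterministic seed substreams.

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible substream seed from a master seed and integer tags.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  x <- as.double(seed) %% 2147483647
  for (t in tags) x <- (x * 69069 + as.double(t) + 1) %% 2147483647
  as.integer(x)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
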