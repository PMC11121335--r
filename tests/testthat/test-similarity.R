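test_that("binary_vector marks member positions in fixed order", {
  space <- c("G1", "G2", "G3")
  expect_identical(binary_vector("G2", space),
                   c(G1 = 0L, G2 = 1L, G3 = 0L))
  expect_identical(unname(binary_vector(character(0), space)), c(0L, 0L, 0L))
  expect_identical(unname(binary_vector(space, space)), c(1L, 1L, 1L))
  expect_error(binary_vector("G9", space), "not in feature space")
})

test_that("acs handles the hand-checked cases", {
  expect_equal(acs(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(acs(c(1, 0), c(0, 1)), -1)
  # phi from the 2x2 table n11=1, n10=1, n01=1, n00=2 is 1/6
  expect_equal(acs(c(1, 1, 0, 0, 0), c(1, 0, 1, 0, 0)), 1 / 6,
               tolerance = 1e-15)
  expect_error(acs(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(acs(1, 1), "length >= 2")
})

test_that("acs equals the phi coefficient and is permutation-equivariant", {
  set.seed(71)
  n_checked <- 0
  while (n_checked < 300) {
    len <- sample(2:50, 1)
    d1 <- runif(1, 0.1, 0.9); d2 <- runif(1, 0.1, 0.9)
    a <- rbinom(len, 1, d1); b <- rbinom(len, 1, d2)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    n_checked <- n_checked + 1
    expect_equal(acs(a, b), phi_oracle(a, b), tolerance = 1e-12)
    p <- sample.int(len)
    expect_identical(acs(a, b), acs(a[p], b[p]))
  }
})

test_that("degenerate vectors return the defined fallback, never NaN", {
  expect_identical(acs(c(0, 0, 0), c(1, 0, 1)), 0)
  expect_identical(acs(c(1, 1, 1), c(1, 0, 1)), 0)
  expect_identical(acs(c(0, 0), c(1, 1)), 0)
})

test_that("level_similarity is symmetric, bounded, unit-diagonal", {
  sets <- list(A = c("x", "y"), B = c("y", "z"), C = c("q", "r"),
               D = c("x", "y"))
  space <- c("q", "r", "x", "y", "z", "w")
  sim <- level_similarity(sets, space, "gene")
  v <- sim$values
  expect_identical(v, t(v))
  expect_true(all(v >= -1 & v <= 1))
  expect_true(all(is.finite(v)))
  expect_equal(unname(diag(v)), rep(1, 4))
  expect_equal(v["A", "D"], 1)  # identical non-constant profiles
  # every off-diagonal entry equals the pairwise phi oracle
  for (i in names(sets)) for (j in names(sets)) {
    if (i == j) next
    expect_equal(v[i, j],
                 phi_oracle(binary_vector(sets[[i]], space),
                            binary_vector(sets[[j]], space)),
                 tolerance = 1e-12)
  }
})

test_that("degenerate profiles score 0 off-diagonal but 1 on the diagonal", {
  sets <- list(A = c("x", "y"), B = character(0),
               C = c("q", "r", "x", "y", "z"))
  space <- c("q", "r", "x", "y", "z")
  expect_message(sim <- level_similarity(sets, space, "gene"), "2 degenerate")
  expect_equal(sim$values["A", "B"], 0)
  expect_equal(sim$values["A", "C"], 0)  # C is all-ones: constant
  expect_equal(sim$values["B", "B"], 1)
  expect_identical(unname(sim$degenerate), c(FALSE, TRUE, TRUE))
})

test_that("combined_similarity averages levels with single-level fallback", {
  mk <- function(vals, degenerate) {
    ids <- rownames(vals)
    structure(list(ids = ids, values = vals, level = "gene",
                   degenerate = stats::setNames(degenerate, ids)),
              class = "ddcm_similarity")
  }
  ids <- c("A", "B", "C")
  g <- matrix(c(1, .4, .2, .4, 1, .6, .2, .6, 1), 3, 3,
              dimnames = list(ids, ids))
  p <- matrix(c(1, .6, 0, .6, 1, 0, 0, 0, 1), 3, 3,
              dimnames = list(ids, ids))
  # C is degenerate at the pathway level -> its pairs fall back to gene-only
  sim <- combined_similarity(mk(g, c(FALSE, FALSE, FALSE)),
                             mk(p, c(FALSE, FALSE, TRUE)))
  expect_equal(sim$values["A", "B"], 0.5)     # mean(0.4, 0.6)
  expect_equal(sim$values["A", "C"], 0.2)     # gene-only fallback
  expect_equal(sim$values["B", "C"], 0.6)
  expect_equal(unname(diag(sim$values)), rep(1, 3))
  # both levels degenerate -> 0
  sim2 <- combined_similarity(mk(g, c(FALSE, FALSE, TRUE)),
                              mk(p, c(FALSE, FALSE, TRUE)))
  expect_equal(sim2$values["A", "C"], 0)
  expect_true(sim2$degenerate[["C"]])
  # mismatched IDs error
  gg <- mk(g, rep(FALSE, 3)); gg$ids <- c("A", "B", "X")
  expect_error(combined_similarity(gg, mk(p, rep(FALSE, 3))), "ID orderings")
})

test_that("similarity matrices round-trip through TSV", {
  ds <- make_tiny_dataset()
  sim <- suppressMessages(
    level_similarity(ds$disease_genes, ds$spaces$disease_gene, "gene"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_similarity(sim, tmp)
  back <- read_similarity(tmp, "gene")
  expect_identical(back$ids, sim$ids)
  expect_equal(back$values, sim$values, tolerance = 1e-12)
})

test_that("dataset similarity matrices never contain NaN or Inf", {
  synth <- generate_synthetic(synthetic_config(
    n_diseases = 8L, n_drugs = 20L, n_genes = 80L, n_pathways = 24L,
    n_clusters = 2L, drugs_per_disease = 1L, seed = 5L))
  sims <- suppressMessages(dataset_similarities(synth$dataset))
  for (m in list(sims$disease$values, sims$drug$values)) {
    expect_true(all(is.finite(m)))
    expect_true(all(m >= -1 & m <= 1))
    expect_identical(m, t(m))
  }
})
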