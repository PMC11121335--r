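fake_scores <- function(drug_ids, scores, disease = "D1") {
  st <- data.frame(disease_id = disease, drug_id = drug_ids, score = scores,
                   stringsAsFactors = FALSE)
  class(st) <- c("ddcm_scores", "data.frame")
  st
}

test_that("top_candidates takes the k best with deterministic tie-breaks", {
  ids <- sprintf("R%02d", 1:60)
  st <- fake_scores(ids, seq(60, 1))   # distinct scores, R01 highest
  top <- top_candidates(st, 50)
  expect_equal(nrow(top), 50)
  expect_identical(top$drug_id, ids[1:50])
  expect_identical(top$rank, 1:50)

  st30 <- fake_scores(sprintf("R%02d", 1:30), rnorm(30))
  expect_equal(nrow(top_candidates(st30, 50)), 30)

  # tie at the boundary: equal scores at ranks 2-3, k = 2
  st_tie <- fake_scores(c("Rb", "Ra", "Rz"), c(5, 1, 1))
  top2 <- top_candidates(st_tie, 2)
  expect_identical(top2$drug_id, c("Rb", "Ra"))  # smaller ID wins the tie
})

test_that("stability_score is 1 minus the sample spread of indicators", {
  expect_equal(stability_score(c(1, 1, 1, 1)), 1)
  expect_equal(stability_score(c(0, 0, 0, 0)), 1)
  expect_equal(stability_score(c(1, 1, 0, 0)), 1 - sqrt(1 / 3),
               tolerance = 1e-15)
  expect_equal(stability_score(c(1, 0), variant = "variance"), 0.5)
  expect_error(stability_score(1), "M >= 2")
  expect_error(stability_score(c(1, 2)), "0/1")
})

test_that("perturbation runs are seeded, sized, and never remove the query", {
  ds <- make_planted_dataset()
  sims <- suppressMessages(dataset_similarities(ds))
  cfg <- screen_config(k = 5, M = 3, seed = 1)
  train <- build_training_matrix(ds, sims$drug, sims$disease, seed = 1)

  runs <- run_perturbations(train, "D1", j = 1, M = 3, seed = 7,
                            drug_sim = sims$drug, disease_sim = sims$disease,
                            config = cfg)
  expect_length(runs, 3)
  expect_true(all(vapply(runs, function(r) length(r$removed_diseases), 0L) == 1))

  runs2 <- run_perturbations(train, "D1", j = 1, M = 3, seed = 7,
                             drug_sim = sims$drug, disease_sim = sims$disease,
                             config = cfg)
  expect_identical(lapply(runs, `[`, c("removed_diseases", "top")),
                   lapply(runs2, `[`, c("removed_diseases", "top")))

  # the sampler never touches the query disease, across many seeded runs
  many <- run_perturbations(train, "D1", j = 2, M = 40, seed = 13,
                            drug_sim = sims$drug, disease_sim = sims$disease,
                            config = cfg)
  removed <- unlist(lapply(many, `[[`, "removed_diseases"))
  expect_false("D1" %in% removed)
  expect_true(all(vapply(many, function(r)
    length(r$removed_diseases) == 2 && !anyDuplicated(r$removed_diseases), TRUE)))

  expect_error(
    run_perturbations(train, "D1", j = 7, M = 2, seed = 1,
                      drug_sim = sims$drug, disease_sim = sims$disease,
                      config = cfg),
    "must be <")
  expect_error(
    run_perturbations(train, "D1", j = 1, M = 1, seed = 1,
                      drug_sim = sims$drug, disease_sim = sims$disease,
                      config = cfg),
    "M must be >= 2")
})

test_that("stability, intersection and total-stability cuts match brute force", {
  # constructed 20-drug fixture, M = 4 runs per regime
  drugs <- sprintf("R%02d", 1:20)
  drc <- top_candidates(fake_scores(drugs, seq(20, 1)), k = 18)  # R01..R18
  set.seed(33)
  mk_runs <- function(present_prob) {
    lapply(1:4, function(i) {
      list(removed_diseases = "Dx",
           top = drugs[runif(20) < present_prob])
    })
  }
  runs <- list("1" = mk_runs(0.9), "2" = mk_runs(0.8), "5" = mk_runs(0.6))
  cfg <- screen_config(k = 18, M = 4, seed = 1)
  tab <- stability_table(drc, runs, cfg)

  # brute force, computed independently from the raw run lists
  for (r in c("1", "2", "5")) {
    for (d in drugs) {
      ind <- vapply(runs[[r]], function(x) as.numeric(d %in% x$top), 0)
      expect_equal(tab[[paste0("S", r)]][tab$drug_id == d],
                   1 - two_pass_sd(ind), tolerance = 1e-12)
      expect_equal(tab[[paste0("eligible", r)]][tab$drug_id == d],
                   sum(ind) > 0)
    }
  }
  # total stability over M' = 3M + 1 indicators (the +1 is DrC membership)
  for (d in drugs) {
    ind <- c(unlist(lapply(c("1", "2", "5"), function(r)
      vapply(runs[[r]], function(x) as.numeric(d %in% x$top), 0))),
      as.numeric(d %in% drc$drug_id))
    expect_length(ind, 13)
    expect_equal(tab$SSDrC[tab$drug_id == d], 1 - two_pass_sd(ind),
                 tolerance = 1e-12)
  }

  sdrc <- stable_candidates(tab, drc, cfg)
  brute_drsj <- lapply(c("1", "2", "5"), function(r) {
    s <- tab[[paste0("S", r)]]; elig <- tab[[paste0("eligible", r)]]
    ids <- tab$drug_id[elig]; s <- s[elig]
    thr <- sort(s, decreasing = TRUE)[ceiling(0.95 * length(s))]
    ids[s >= thr]
  })
  expect_setequal(sdrc,
                  Reduce(intersect, c(brute_drsj, list(drc$drug_id))))

  ptdr <- potential_drugs(tab, sdrc, cfg)
  s <- tab$SSDrC[match(sdrc, tab$drug_id)]
  thr <- sort(s, decreasing = TRUE)[ceiling(0.95 * length(s))]
  expect_setequal(ptdr, sdrc[s >= thr])

  # membership rules: in every DrSj and DrC -> in; missing one DrSj -> out
  in_all <- Reduce(intersect, brute_drsj)
  if (length(in_all)) {
    d_in <- intersect(in_all, drc$drug_id)[1]
    expect_true(d_in %in% sdrc)
  }
  only_out <- setdiff(intersect(drc$drug_id, brute_drsj[[1]]), brute_drsj[[2]])
  if (length(only_out)) expect_false(only_out[1] %in% sdrc)
})

test_that("a drug present in every run always survives the total cut", {
  drugs <- c("Ra", "Rb", "Rc")
  drc <- top_candidates(fake_scores(drugs, 3:1), k = 3)
  runs <- lapply(c("1", "2", "5"), function(r)
    lapply(1:3, function(i) list(removed_diseases = "Dx",
                                 top = c("Ra", sample(drugs, 1)))))
  names(runs) <- c("1", "2", "5")
  cfg <- screen_config(k = 3, M = 3, seed = 1)
  tab <- stability_table(drc, runs, cfg)
  expect_equal(tab$SSDrC[tab$drug_id == "Ra"], 1)
  sdrc <- stable_candidates(tab, drc, cfg)
  expect_true("Ra" %in% potential_drugs(tab, sdrc, cfg))
})

test_that("an empty stable-candidate set yields an empty warned result", {
  drc <- top_candidates(fake_scores(c("Ra", "Rb"), 2:1), k = 2)
  runs <- lapply(c("1", "2", "5"), function(r)
    lapply(1:2, function(i) list(removed_diseases = "Dx", top = "Ra")))
  names(runs) <- c("1", "2", "5")
  cfg <- screen_config(k = 2, M = 2, seed = 1)
  tab <- stability_table(drc, runs, cfg)
  expect_warning(out <- potential_drugs(tab, character(0), cfg), "empty")
  expect_length(out, 0)
})

test_that("the full screen recovers a planted twin of a known drug", {
  ds <- make_planted_dataset()
  cfg <- screen_config(k = 4, M = 3, seed = 5)
  res <- suppressMessages(screen_disease(ds, "D1", cfg))
  # R02 is profile-identical to D1's known drug R01: it must survive the
  # entire stepwise screen
  expect_true("R02" %in% res$candidates$drug_id)
  expect_true("R02" %in% res$ptdr)
  # containment chain
  expect_true(all(res$ptdr %in% res$sdrc))
  expect_true(all(res$sdrc %in% res$candidates$drug_id))
})

test_that("screening twice with one seed is identical end to end", {
  ds <- make_planted_dataset()
  cfg <- screen_config(k = 4, M = 3, seed = 9)
  r1 <- suppressMessages(screen_disease(ds, "D1", cfg))
  r2 <- suppressMessages(screen_disease(ds, "D1", cfg))
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$stability, r2$stability)
  expect_identical(r1$ptdr, r2$ptdr)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_screen_results(r1, d1)
  write_screen_results(r2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})
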