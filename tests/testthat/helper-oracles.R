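# Independent oracles used across the suite. These deliberately take
# different computational routes than the package code they check.

# Phi coefficient of two binary vectors via the 2x2 contingency table:
# (n11*n00 - n10*n01) / sqrt(n1. * n0. * n.1 * n.0)
phi_oracle <- function(a, b) {
  n11 <- sum(a == 1 & b == 1)
  n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1)
  n00 <- sum(a == 0 & b == 0)
  den <- sqrt(n11 + n10) * sqrt(n01 + n00) * sqrt(n11 + n01) * sqrt(n10 + n00)
  (n11 * n00 - n10 * n01) / den
}

# Two-pass sample standard deviation (explicit mean pass then spread pass).
two_pass_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Independent eps-SVR solve via libsvm (e1071). Returns the optimal value
# of the primal QP obtained through strong duality from libsvm's converged
# dual solution (its dual objective is far more precise than its reported
# intercept).
libsvm_svr_optimum <- function(X, y, cost, epsilon) {
  m <- e1071::svm(x = X, y = y, type = "eps-regression", kernel = "linear",
                  cost = cost, epsilon = epsilon, scale = FALSE,
                  tolerance = 1e-10)
  beta <- numeric(length(y))
  beta[m$index] <- m$coefs
  K <- tcrossprod(X)
  dual <- 0.5 * drop(t(beta) %*% K %*% beta) + epsilon * sum(abs(beta)) -
    sum(y * beta)
  list(optimum = -dual,
       w = as.vector(crossprod(m$coefs, m$SV)),
       b = -m$rho)
}

# Mann-Whitney AUC by exhaustive pair counting (ties count one half).
auc_pairwise_oracle <- function(score, is_pos) {
  pos <- score[is_pos]; neg <- score[!is_pos]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Small fully hand-specified dataset: 4 diseases, 6 drugs, two levels each.
make_tiny_dataset <- function() {
  dg <- list(D1 = c("G1", "G2", "G3"), D2 = c("G2", "G3", "G4"),
             D3 = c("G5", "G6"), D4 = c("G6", "G7", "G8"))
  dp <- list(D1 = c("P1", "P2"), D2 = c("P1", "P3"),
             D3 = c("P3", "P4"), D4 = c("P4"))
  rg <- list(R1 = c("H1", "H2"), R2 = c("H2", "H3"), R3 = c("H4", "H5"),
             R4 = c("H5", "H6"), R5 = c("H1", "H7"), R6 = c("H8", "H9", "H10"))
  rp <- list(R1 = c("Q1"), R2 = c("Q1", "Q2"), R3 = c("Q3"),
             R4 = c("Q3", "Q4"), R5 = c("Q5"), R6 = c("Q2", "Q5"))
  assoc <- data.frame(
    disease_id = c("D1", "D2", "D3", "D4", "D1"),
    drug_id = c("R1", "R2", "R3", "R4", "R5"),
    source = NA_character_, stringsAsFactors = FALSE)
  suppressMessages(assemble_dataset(dg, dp, rg, rp, assoc))
}

# Screening-scale planted fixture: drug R02's profiles are byte-identical
# to R01's, and R01 is a known drug for the query disease D1 and two other
# diseases (making it the dominant therapeutic pattern), so R02 must ride
# R01's similarity through the whole pipeline.
make_planted_dataset <- function(n_extra_drugs = 8, n_diseases = 8, seed = 404) {
  with_seed(seed, {
    genes <- sprintf("G%02d", 1:40)
    drug_genes_space <- sprintf("H%02d", 1:40)
    pathways <- sprintf("P%02d", 1:10)
    drug_pathways_space <- sprintf("Q%02d", 1:10)
    diseases <- sprintf("D%d", seq_len(n_diseases))
    dg <- dp <- list()
    for (d in diseases) {
      dg[[d]] <- sample(genes, 6)
      dp[[d]] <- sample(pathways, 3)
    }
    drugs <- sprintf("R%02d", seq_len(2 + n_extra_drugs))
    rg <- rp <- list()
    rg[["R01"]] <- sample(drug_genes_space, 6)
    rp[["R01"]] <- sample(drug_pathways_space, 3)
    rg[["R02"]] <- rg[["R01"]]  # planted twin
    rp[["R02"]] <- rp[["R01"]]
    for (r in drugs[-(1:2)]) {
      rg[[r]] <- sample(drug_genes_space, 6)
      rp[[r]] <- sample(drug_pathways_space, 3)
    }
    n_anchor <- n_diseases - 2L
    assoc <- data.frame(
      disease_id = diseases,
      drug_id = c(rep("R01", n_anchor),
                  sample(drugs[-(1:2)], n_diseases - n_anchor)),
      source = NA_character_, stringsAsFactors = FALSE)
    suppressMessages(assemble_dataset(dg, dp, rg, rp, assoc))
  })
}
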