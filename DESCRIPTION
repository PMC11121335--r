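Package: ddcm
Title: Disease-Drug Correlation Scoring and Stable Candidate Screening for Drug Repositioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores disease-drug therapeutic correlations by training
    epsilon-insensitive support-vector regression on a hybrid matrix of
    drug-drug and disease-disease similarities (adjusted cosine over binary
    gene and pathway membership profiles), then screens stable potential
    therapeutic drugs through a randomized-perturbation, stepwise filtering
    pipeline. Includes readers for GMT gene-set and TSV association files, a
    synthetic benchmark generator with planted held-out associations, and an
    AUC-based recovery evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
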