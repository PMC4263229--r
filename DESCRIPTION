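Package: cormotif
Title: Correlation Motifs for Joint Differential Expression Analysis Across Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Jointly detects differential gene expression across multiple
    two-condition studies. Each study is summarised by empirical-Bayes
    moderated t-statistics; a small number of latent probability vectors
    ("correlation motifs") then captures the major cross-study correlation
    patterns of differential expression through a hierarchical mixture model
    fitted by MAP-EM under Dirichlet/Beta priors, with BIC selection of the
    motif number. Includes the in-family baseline models (per-study limma-style
    mixture, all-concordant model, saturated full-motif model), a seeded
    model-based simulation generator with ground truth, and evaluation
    utilities (posterior gene ranking, true-positive curves, configuration
    confusion matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    limma,
    stats,
    utils,
    tibble,
    rlang,
    generics,
    ggplot2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
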