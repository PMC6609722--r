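Package: pcmnet
Title: Pharmacometabolomic Partial-Correlation Network Analysis of Antidepressant Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal pharmacometabolomics of SSRI treatment in
    depression: simulation of cohorts with known metabolite network structure,
    preprocessing (missingness QC, k-nearest-neighbour imputation, log2
    unit-variance scaling, HRSD-17 response labelling), per-metabolite
    linear mixed-model scans with Benjamini-Hochberg false-discovery control,
    two-step time-course regression separating responder and nonresponder
    profiles, EBIC-regularised Gaussian graphical model (graphical lasso)
    partial-correlation networks with bootstrap aggregation, walktrap
    community detection and permutation-based differential network
    comparison, and covariate-adjusted additive genetic association scans
    for metabolite-ratio traits with variant quality control.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    lme4,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
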