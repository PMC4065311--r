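Package: immunosig
Title: Immunosignature Analysis of Random-Sequence Peptide Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis workflow for immunosignaturing: serum antibody binding
    profiles on random-sequence peptide microarrays used to diagnose and
    predict murine lupus and its CNS behavioral manifestations. Reads GenePix
    Results (GPR) intensity files, median-normalizes and log10-transforms
    slides, computes array quality-control statistics, selects diagnostic and
    predictive peptide signatures with binding-ratio mean + k*SD threshold
    rules and cross-study intersection, evaluates signatures by leave-one-out
    cross-validated linear support vector machines, and maps signature
    peptides to candidate protein targets by gapless local alignment against
    a proteome with empirical permutation p-values. A calibrated synthetic
    cohort generator reproduces the arrays' published noise structure so the
    full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
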