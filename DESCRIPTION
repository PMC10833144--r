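Package: urinepanel
Title: Urinary Peptide Biomarker Discovery and Panel Classification for
    Primary FSGS
Version: 0.1.0
Authors@R:
    person("Urinepanel", "Developers", email = "urinepanel@example.org",
           role = c("aut", "cre"))
Description: A reusable implementation of a CE-MS urinary-peptidome workflow
    for discriminating primary from secondary focal segmental
    glomerulosclerosis (FSGS). Provides the packaged 93-peptide diagnostic
    panel with its per-group summary statistics, a three-stage differential
    abundance filter (Wilcoxon rank-sum screening against normal controls
    with Benjamini-Hochberg adjustment, followed by direction-consistent
    confirmation against secondary FSGS and other chronic kidney diseases),
    a linear support-vector-machine panel classifier with leave-one-out
    cross-validation, greedy backward feature elimination and Youden-index
    cutoff selection, ROC/AUC machinery with DeLong confidence intervals and
    paired tests, covariable logistic regression and a two-term nomogram,
    and a seeded zero-inflated log-normal cohort simulator calibrated to the
    published panel intensities for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    quadprog,
    optparse,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
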