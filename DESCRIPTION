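Package: adgenrisk
Title: Two-Stage Genetic Risk Scoring and ROC Decision Trees for
    Heterogeneous Case/Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-stage candidate-gene risk studies of clinically
    heterogeneous case/control cohorts such as amnestic versus atypical
    Alzheimer's disease. Provides marker quality control (call rate, minor
    allele frequency, exact Hardy-Weinberg test), per-marker additive
    logistic association scans with Bonferroni correction, greedy linkage
    disequilibrium pruning, nested risk-allele score sets with an
    AUC-based stopping rule evaluated by DeLong's method, kappa-weighted
    ROC recursive-partitioning decision trees, and a calibrated
    case/control genotype simulator for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
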