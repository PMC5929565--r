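Package: perturbnet
Title: Individual-Specific miRNA-lncRNA Networks by Single-Sample
    Correlation Perturbation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds individual-specific miRNA-lncRNA networks (ISMLNs) by
    measuring how the Pearson correlation of each catalogued miRNA-lncRNA
    pair changes when a single case sample is appended to a reference
    cohort of control samples (the delta-PCC statistic), aggregates the
    per-sample networks into a per-cohort basic miRNA-lncRNA network
    (BMLN) through edge significance scores, ranks candidate edge
    biomarkers with random-forest feature importance evaluated by
    stratified cross-validated ROC/AUC, computes per-miRNA Activity
    Scores, and provides a differential-expression node-biomarker
    baseline plus a synthetic cohort generator with planted correlation
    perturbations so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
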