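Package: lymphcascade
Title: Cascade Random-Forest Classification of Small B-Cell Lymphoid Neoplasms from Digital Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and applying a multi-step molecular classifier
    of small B-cell lymphoid neoplasms (SBCLNs) from NanoString-style digital
    gene expression counts. Implements housekeeping-gene selection by the
    geNorm stability statistic, geometric-mean normalization with log2
    transform, differential-expression marker screening, a Davies-Bouldin-
    ordered cascade of one-vs-rest binary random forests with Gini-importance
    marker refinement and an "undetermined" fallback, tumor-purity cutoff
    calibration, integration of entity-specific genetic markers (IGH-BCL2,
    MYD88 L265P, BRAF V600E, EZH2 Y646), and a negative-binomial synthetic
    cohort simulator with tumor-purity mixing for end-to-end testing without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
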