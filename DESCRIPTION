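Package: methylDelta
Title: Longitudinal Blood Methylation Analysis by Per-Patient Delta-Beta
    Consensus Calling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal analysis of Illumina EPIC-style DNA
    methylation beta-value matrices. Implements a per-patient delta-beta
    consensus caller for diet-responsive CpG sites, global methylation
    summaries (medians, PCA, clinical correlations), genomic-feature
    enrichment fold changes with a resampling null, fibrosis-grade
    stratification of liver methylomes (Ward clustering with a chi-squared
    cluster-by-grade test and a seeded gradient-boosted tree classifier
    with cross-validated ROC), a longitudinal clinical-parameter testing
    engine, and a fully seeded synthetic cohort generator with a planted
    ground-truth ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    car,
    pROC,
    xgboost
Suggests: testthat (>= 3.0.0), knitr, rmarkdown, jsonlite, optparse,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics,
    MethylationArray, Classification, Clustering
RoxygenNote: 7.3.3
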