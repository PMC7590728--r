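Package: epiclock
Title: Building and Evaluating Blood-Based Epigenetic Clocks from
    Methylation Array Beta Values
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to construct, apply, and evaluate sparse linear
    predictors of chronological age ("epigenetic clocks") from Illumina
    methylation-array beta values. Provides elastic-net training with
    cross-validated penalty selection via a coordinate-descent solver,
    probe quality-control cascades (sex chromosomes, cross-hybridizing
    probes, detection p-values, SNP-proximal probes, 450K/EPIC platform
    restriction), application of clocks through portable coefficient
    files, precision/accuracy metrics (Pearson r with Fisher-Z bootstrap
    intervals, median absolute prediction error), epigenetic age
    acceleration with linear, piecewise-cubic, and smoothing-spline
    calibration, a beta-distributed synthetic cohort simulator for
    validation without access-restricted data, and a paired subsampling
    experiment comparing probe sets across training-set sizes with
    spline-smoothed learning curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    mgcv,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epigenetics, DNAMethylation, MethylationArray, Regression,
    Software
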