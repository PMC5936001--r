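Package: rpoutliers
Title: Ensemble Model-Based Outlier Detection with the Rank Product Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects outlying observations in high-dimensional two-class
    expression data by combining influence diagnostics from an ensemble of
    sparse classifiers. Elastic-net logistic regression, sparse partial least
    squares discriminant analysis (SPLS-DA) and sparse generalized PLS (SGPLS)
    are fitted to the same samples; each observation's influence on each model
    is scored by Cook's distance, per-model outlierness rankings are combined
    with the Rank Product statistic, and consensus outliers are called from
    exact or bounded null p-values with Benjamini-Hochberg q-values. Includes
    resampling ensembles over patients and over features, consensus gene
    selection, receptor-status (TNBC) label construction with HER2 assay
    precedence, and a synthetic label-flip benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
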