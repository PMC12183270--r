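Package: magat
Title: Multi-Atlas Ensemble Graph Attention Networks for Functional
    Connectome Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying subjects (major depressive disorder
    versus healthy control) from region-of-interest rs-fMRI time series
    parcellated with several brain atlases. The pipeline covers
    empirical-Bayes ComBat harmonization of multi-site data, class-wise
    SMOTE oversampling of time-series matrices, Pearson/Fisher-z
    functional-connectivity network construction, k-nearest-neighbour
    brain-graph generation, per-atlas graph attention network (GAT)
    classifiers trained with Adam, and ensemble aggregation by majority
    voting, probability sum and validation-accuracy-weighted sum, under
    stratified cross-validation. A multi-site synthetic-cohort generator
    with known site effects and class-dependent connectivity supports
    benchmarking when clinical data are access-restricted.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    Matrix,
    withr
Suggests:
    testthat (>= 3.0.0),
    sva,
    yaml,
    jsonlite
Config/testthat/edition: 3
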