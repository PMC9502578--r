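Package: ciperm
Title: Ensemble QSAR Modeling of Ex Vivo Placental Barrier Permeability
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds quantitative structure-activity relationship (QSAR)
    regression models of the placental clearance index (CI), the ex vivo
    permeability of a chemical across the perfused human placenta relative
    to antipyrine. Provides descriptor-table import with strict validation,
    removal of uninformative descriptors (extreme values, scarcity, low
    variation), z-score normalization with training-derived parameters,
    leave-one-out cross-validated sequential forward feature selection, a
    voting ensemble of ordinary least squares and a seed-deterministic
    random forest, a regression-tree applicability domain learned from
    cross-validation errors of the training set only, and a synthetic-data
    generator emulating the small-n wide descriptor tables the workflow is
    designed for.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    rpart,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    ranger,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
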