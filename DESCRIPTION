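Package: aquasol
Title: Aqueous Solubility QSPR Modelling with Molecular Descriptors and
    Morgan Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantitative structure-property relationship (QSPR) pipeline
    for predicting the aqueous solubility (logS, log10 mol/L) of low
    molecular weight organic compounds, comparing two chemical
    representations: continuous 2D molecular descriptors and 2048-bit
    Morgan (ECFP4) circular fingerprints. Provides dataset curation of
    merged literature solubility sources, a 2D descriptor engine with a
    variance/correlation pruning cascade, Morgan fingerprinting with a
    bit-to-substructure atlas, LASSO bit selection, random forest and
    multiple linear regression models, exact TreeSHAP feature attribution,
    Local Outlier Factor diagnostics, per-fragment hydration Gibbs-energy
    scoring, blind-set evaluation, and a synthetic molecule generator with
    a planted structure-logS relationship for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    glmnet,
    jsonlite,
    randomForest,
    Rcpp,
    graphics,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
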