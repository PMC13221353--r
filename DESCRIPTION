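Package: dfpi
Title: Dual-Forest Proximity Imputation and Missingness-Pattern Methods for
    Propensity Score Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Propensity score analysis with confounders that are missing not
    at random (MNAR). Implements dual-forest proximity imputation (DFPI), an
    iterative pre-imputation method that averages proximity matrices from a
    treatment-prediction forest and an outcome-prediction forest fitted on
    covariates augmented with missing indicators, together with six
    comparison strategies: missingness-pattern propensity models (MP-LR,
    MP-RF) with Qu-Lipkovich pattern pooling, multiple imputation with
    missing indicators (MIMP-LR, MIMP-RF) via chained equations with
    predictive mean matching, and supervised/unsupervised random-forest
    proximity imputation (PI-I, PI-U). Includes inverse-probability-of-
    treatment weighting with Taylor-linearized standard errors, Rubin's-rule
    pooling, covariate balance diagnostics, a calibrated Monte Carlo
    data-generating process covering MAR and five MNAR mechanisms, and a
    simulation-study driver with relative-bias, mean-squared-error and
    factorial effect-size summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    ranger,
    sandwich,
    glmnet,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
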