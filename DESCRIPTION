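Package: lrho
Title: Regression Modeling of Spearman's Rho for Longitudinal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Regression-based estimation and inference for Spearman's rank
    correlation between two longitudinal outcomes. Represents the grade
    correlation through a three-subject concordance kernel and models its
    Fisher-z type transform as a function of visit indicators and triplet-level
    covariates within a functional response model. Estimation uses U-statistics
    based generalized estimating equations (UGEE) over subject triplets, with
    robust sandwich standard errors. Monotone missing-at-random dropout is
    handled by inverse-probability-weighted estimating equations (UWGEE) with a
    jointly estimated sequential-logistic dropout model, an MCAR diagnostic
    test, and a joint sandwich covariance that propagates dropout-model
    uncertainty. Includes Wald tests for group differences and time trends,
    correlation-scale confidence intervals, two-stage multi-feature screening,
    and a Monte Carlo simulation harness with calibrated dropout designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    MASS,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
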