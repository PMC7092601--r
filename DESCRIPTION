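Package: mvqol
Title: Multivariate Multilevel Models for Longitudinal Quality-of-Life
    Domain Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint estimation of linear growth curves for the four
    WHOQOL-HIV BREF quality-of-life domains (physical health,
    psychological, level of independence, social relationships) with
    correlated subject-level random intercepts and slopes and correlated
    occasion-level residuals, fitted by marginal maximum likelihood with
    a log-Cholesky covariance parameterisation. Includes WHOQOL domain
    scoring and visit-inclusion filters, factor-analytic compression of
    clinical laboratory panels, fit-statistic model comparison between
    related- and independent-outcome formulations, Wald contrasts of
    covariate effects across outcomes, Cholesky-transformed residual
    diagnostics, and a seed-reproducible longitudinal cohort simulator
    for validating the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
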