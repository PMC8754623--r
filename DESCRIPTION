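Package: nutridecomp
Title: Decomposition of Change in Child Underweight Between Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing change in child underweight prevalence
    between repeated cross-sectional household surveys, in the style of
    Demographic and Health Survey (DHS) trend studies. Provides
    weight-for-age Z-score classification, survey-weighted logistic
    regression with a sandwich covariance, a nonlinear (logit-link)
    Blinder-Oaxaca multivariate decomposition of the prevalence
    difference into endowment and coefficient components with
    per-covariate detailed contributions, reference-category (deviation)
    normalisation, delta-method standard errors and percentage shares,
    stratified prevalence trend tables with phase differences, and a
    seeded synthetic two- or three-survey generator with exact
    enumerated ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
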