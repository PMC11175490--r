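Package: finestrat
Title: Design-Based Variance Estimation Under Fine Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variance estimation for Horvitz-Thompson totals in stratified
    surveys with one or two primary sampling units per stratum ("fine
    stratification"). Implements the collapsed-stratum estimator, a
    kernel-weighted neighbourhood estimator with Epanechnikov weights, and a
    bootstrap-based estimator built on pseudo-strata with a bootstrap bias
    corrector, together with exact design enumeration on small populations,
    a synthetic-population generator for seven benchmark mean functions, and
    unconditional and conditional (grouped by the sample mean of the
    auxiliary variable) simulation studies comparing the estimators by bias,
    RMSE and coefficient of variation.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
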