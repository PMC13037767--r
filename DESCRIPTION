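Package: wearmiss
Title: Diagnosing the Missingness Mechanism in Wearable Sleep Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for characterising and diagnosing the likely mechanism of
    missing data (MCAR versus MAR) in repeated-measures nightly sleep data from
    wearable fitness trackers. Provides missingness-pattern enumeration and
    rate tables, Little's MCAR test implemented from its definition (EM
    estimation of a multivariate-normal mean and covariance under incomplete
    data, then the pattern-wise quadratic-form statistic), a random-forest
    missingness classifier built on a cluster-adjusted bootstrap that resamples
    participants rather than nights, generalized estimating equations (GEE)
    logistic regression with robust sandwich standard errors, QIC-based working
    correlation selection and forward variable selection, cross-model agreement
    tables, a mechanism decision rule, and a synthetic-data generator that
    emulates a five-night actigraphy cohort with controllable MCAR/MAR/MNAR
    missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    sandwich,
    mvtnorm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
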