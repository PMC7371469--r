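Package: misshift
Title: Prediction Model Performance Under Shifting Missing-Data Mechanisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for studying how clinical prediction models
    that exploit informative missingness (for example via missing-indicator
    terms) gain or lose predictive performance when the missing-data
    mechanism changes between model development and deployment. Generates
    synthetic cohorts with a known logistic risk model and a missingness
    mechanism that may depend on both observed and unobserved predictors,
    implements four missing-data handling strategies (zero imputation with
    indicator, mean imputation with indicator, complete-case analysis, and
    single-draw predictive mean matching), fits logistic prediction models,
    and evaluates them with prediction error, the c-statistic, the Brier
    score and calibration-in-the-large across deployment scenarios.
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
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
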