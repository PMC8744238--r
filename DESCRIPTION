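Package: logquad5
Title: Log Quadratic Models for Under-Five Age- and Cause-Specific Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits and validates log quadratic models relating cumulative
    probabilities of dying before six under-five age cut points (7 and 28
    days; 6, 12, 24 and 60 months) to under-five mortality, for all-cause
    and cause-specific schedules. Includes the rank-1 age deviation vector
    estimated by singular value decomposition of log-scale residuals, a
    per-life-table shape parameter calibrated to neonatal mortality, a
    constant-hazard baseline, leave-one-stratum-out cross-validation with
    absolute and relative error metrics, a Monte Carlo simulation study of
    parameter recovery and prediction error, and a generator of synthetic
    sample-registration-style life-table collections with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
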