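Package: releaseopt
Title: Parameter Design for Modified-Release Dissolution Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for robust parameter design of modified-release drug
    formulations from replicated dissolution experiments. Computes per-run,
    per-timepoint summary statistics (mean, variance, coefficient of
    variation, inter-timepoint covariance), fits second-order response
    surfaces to each statistic in coded factor space by ordinary least
    squares with optional stepwise screening, and finds factor settings
    maximizing a composite Derringer-Suich desirability against a target
    release profile over a box of coded factor levels. Also provides the
    f1/f2 dissolution similarity indices, a mean-squared-error profile
    objective, a deterministic grid-plus-polish box optimizer, a synthetic
    replicated-experiment generator for validation, and six worked
    formulation case studies shipped as data fixtures.
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
    MASS,
    purrr,
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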