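Package: egmine
Title: Exceptional Growth Mining for On-Farm Longitudinal Crop Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits field-specific logistic growth curves to longitudinal crop
    measurements with a year-stratified nonlinear mixed-effects model
    (maximum marginal likelihood via adaptive Gauss-Hermite quadrature),
    extracts per-field empirical-Bayes random effects for maximum growth,
    steepness, and midpoint timing, and mines interpretable subgroups of
    fields whose random effects deviate exceptionally from zero using
    beam-search exceptional model mining with a t-statistic quality
    measure. Mined subgroups are reduced to the Pareto front over
    directional mean, spread, and size, and profiled against yield,
    irrigation, and planting-period tertiles. Includes a seeded generator
    of farm-like synthetic datasets with correlated random effects and
    descriptor-linked planted subgroups.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
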