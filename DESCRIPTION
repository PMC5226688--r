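Package: pmhindcast
Title: Historical Spatio-Temporal Prediction of Annual Fine Particulate Matter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for predicting annual-average fine particulate matter
    (PM2.5) at arbitrary continental-scale locations over a multi-decade
    window from monitoring data observed mostly in the final years of that
    window. The model decomposes log annual averages into a spatially
    varying long-term mean (geographic covariates reduced by partial least
    squares, residual spatial structure by universal kriging with an
    exponential covariance), a spatially varying coefficient on a single
    temporal trend basis estimated by singular value decomposition and
    extended backwards by linear extrapolation or calibration against
    sulfate-like and visibility-like proxy networks, and spatially kriged
    annual residuals. Includes monitoring quality control with completeness
    and gap criteria, cross-validation and external-validation statistics
    (MSE-based R-squared, RMSE, calibration lines), residence-history
    weighted exposure assignment, and a seeded synthetic-world generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
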