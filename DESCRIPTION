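Package: airerr
Title: Exposure Measurement Error Simulation for Air Pollution Time-Series Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies combined instrument-imprecision and spatial-variability
    error in ambient air pollutant measurements via population-weighted scaled
    semivariograms, injects multiplicative (log-additive) measurement error of
    classical-like, Berkson-like, or intermediate type into a base-case
    exposure series by Monte Carlo simulation, fits overdispersion-scaled
    Poisson health models to daily event counts, and quantifies and predicts
    the resulting bias (attenuation or inflation) in risk ratio estimates per
    measurement unit and per interquartile range. Includes a synthetic-data
    generator that emulates monitor networks, census-tract populations and
    daily emergency-visit counts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
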