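Package: iplslasso
Title: Interval PLS Member Models Fused by Lasso for Spectral Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration of egg freshness (Haugh unit) from visible/short-wave
    near-infrared semi-transmittance spectra by interval partial least squares
    (iPLS) member models whose cross-validated outputs are selected and combined
    by a Lasso regression, swept over interval divisions. Includes spectral
    pretreatments (SNV, MSC, Savitzky-Golay first derivative), outlier screening,
    calibration/prediction splitting, egg-freshness indicators (Haugh unit,
    weight loss rate, yolk coefficient, shape index), stacked-PLS comparators,
    and a synthetic cohort-and-spectra generator with a known freshness-to-
    spectrum link for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
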