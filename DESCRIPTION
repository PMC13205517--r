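Package: facesync
Title: Interindividual Synchrony Analysis of Webcam Facial-Landmark Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying interindividual synchrony from webcam
    facial-landmark recordings captured at irregular sampling rates.
    Provides parsing of landmark CSV exports, preprocessing (missingness
    filtering, linear resampling to a uniform grid, group alignment, head
    movement quantified as per-second nose-tip path length in centimetres),
    Surrogate Synchrony (SUSY) for single-channel dyadic signals
    (segmented lagged cross-correlations, Fisher-Z aggregation, circular
    surrogate null and a Cohen's-d-like effect size), and Correlated
    Component Analysis (CorrCA) for multivariate landmark features
    (shrinkage-regularised generalised eigendecomposition, component,
    per-subject and sliding-window intersubject correlation, forward
    model). Includes seeded simulation generators for injected-synchrony
    validation studies.
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
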