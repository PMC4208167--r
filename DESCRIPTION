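Package: lfaquant
Title: Quantitative Lateral-Flow Strip Reading with Robust Camera-Parameter Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning lateral-flow immunoassay strip images into
    quantitative analyte concentrations. Provides strip densitometry
    (band detection and background-corrected line signals), two-level
    orthogonal-array (Taguchi) screening of camera acquisition parameters
    using the dynamic signal-to-noise statistic, response-table and
    ANOVA factor analysis with interaction diagnostics, linear
    calibration with inverse prediction and precision profiling, and a
    seed-controlled synthetic strip generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
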