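Package: orbidelta
Title: Isotope Ratio Analysis for Orbitrap Mass Spectrometry by
    Sample-Standard Bracketing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes compound-specific carbon isotope ratios (delta-13C)
    from Orbitrap mass spectrometry scan data. Estimates ion counts from
    signal-to-noise readings, forms per-scan isotopologue ratios with
    robust outlier rejection, segments dual-inlet and flow-injection
    sessions into reference and sample blocks, applies sample-standard
    bracketing, and anchors results to the VPDB scale. Includes an exact
    isotopologue fine-structure calculator for arbitrary molecular
    formulas and adducts, and a seeded Poisson shot-noise session
    simulator for method validation and precision prediction.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
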