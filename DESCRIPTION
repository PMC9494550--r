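Package: neutrondose
Title: Out-of-Field Neutron Dose Modelling for Pencil Beam Scanning Proton Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing secondary-neutron ambient dose equivalent
    H*(10) around pencil beam scanning proton therapy treatments:
    lethargy-binned neutron fluence spectra and a parametric spectrum
    generator, fluence-to-H*(10) conversion and ambient-neutron-monitor
    response-function convolution, tissue-equivalent proportional counter
    (TEPC) dose-equivalent algorithms (variance method and single-event
    lineal-energy method), a k = 1 measurement uncertainty budget, a
    per-position multiplicative scaling-law model of out-of-field H*(10)
    versus treatment-plan parameters with an organ-dose estimator, and a
    synthetic measurement-campaign generator for end-to-end testing.
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
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
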