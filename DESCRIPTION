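Package: actinospec
Title: Action and Response Spectroscopy for UVR Exposure of RPE Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds quantitative action and response spectra for ultraviolet
    radiation (UVR) effects on retinal pigmented epithelium (RPE) monolayers.
    Implements control-scaled viability dose-response spectra (squared
    regression slopes normalised to a visible reference wavelength),
    time-to-common-action action spectra from electric cell-substrate
    impedance sensing (ECIS) time series (reciprocal-dose efficiencies at a
    60 percent-of-baseline endpoint), high-content-imaging response spectra
    aggregated by probe compartment and texture kernel, and Monte-Carlo
    reference-based consensus clustering of wavelength responses with
    PAC-based selection of the number of clusters. A synthetic-data module
    generates viability plates, ECIS traces and imaging feature tables with
    planted wavelength-effect profiles so every stage is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
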