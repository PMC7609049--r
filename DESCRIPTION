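Package: organoidhcs
Title: High-Content Image and Time-Series Analysis for 3D Organoid Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantification of whole-mount-stained, cleared 3D
    organoids imaged as multi-channel confocal z-stacks in multiwell plates.
    Implements the four analysis stages of a high-content screening workflow:
    aggregate (sample) identification with quality control, local background
    correction (Gaussian high-pass and sliding-paraboloid opening), nucleus
    and cell segmentation with size/brightness gating, and per-well data
    reporting with plate-level analytics (coefficient of variation,
    edge-effect estimation, dilution-series linearity, subpopulation-specific
    dose-response). Includes functional readouts (calcium spike synchrony,
    field-potential oscillation metrics and spectra) and a synthetic-data
    generator that renders calibrated organoid stacks, plates, and time
    series with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    tiff,
    signal,
    minpack.lm,
    yaml,
    jsonlite,
    zoo,
    Rcpp,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
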