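Package: cypcnt
Title: Monte Carlo Adsorption of Cytochrome P450 on Carbon Nanotubes and
    Voltammetric Biosensor Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the formation of a cytochrome P450 monolayer on
    multi-walled carbon nanotubes by random sequential adsorption of
    triangular-prism protein models, with attachment probabilities
    proportional to the hydrophobic contact area and a buried-surface-area
    enthalpy of -104.5 J/(mol*A^2). Emulates SEM-style coated-diameter
    measurements on the simulated tubes. Also provides a cyclic-voltammetry
    analysis pipeline for P450/nanotube drug biosensors: a synthetic
    voltammogram generator with capacitive hysteresis and Gaussian faradaic
    peaks, baseline-corrected peak-current extraction, linear calibration
    (sensitivity and per-area sensitivity), three-sigma-over-slope detection
    limits, and multi-drug hetero-activation analysis.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
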