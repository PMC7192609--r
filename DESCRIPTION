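Package: dntpquant
Title: Kinetic Quantification of dNTPs from Fluorescent Polymerase Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of single-cycle fluorescent progress curves from
    polymerase-based dNTP incorporation assays. Progress curves are
    decomposed into a fast, dNTP-incorporation phase and a slow,
    background probe-hydrolysis phase by single- and double-exponential
    fitting with small-sample-corrected AIC model selection. dNTP amounts
    are quantified from the fast-phase amplitude via linear plate
    calibration with limit-of-detection and limit-of-quantification
    estimation, six per-well quality-control checkpoints, normalization
    to cell or CFU counts, assay-performance statistics, quadratic
    tight-binding characterization of amplitude competition, and a
    synthetic plate generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
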