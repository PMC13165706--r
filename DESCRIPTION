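Package: nirhoney
Title: Chemometric Calibration and Botanical Classification of Honey NIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for near-infrared (NIR) spectral analysis of honey:
    simulation of reference chemistry and multi-instrument absorbance
    spectra, spectral input/output with replicate averaging, pre-processing
    (SNV, MSC, linear detrending, Savitzky-Golay filtering, centring and
    autoscaling), a NIPALS partial least squares engine with VIP and
    Selectivity Ratio diagnostics, wavelength selection by stepwise interval
    PLS and competitive adaptive reweighted sampling, and multi-algorithm
    calibration and botanical-origin classification evaluated under
    Venetian-blind cross-validation and bootstrap resampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    signal,
    e1071,
    ranger,
    MASS,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
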