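Package: tspeckle
Title: Temporal Speckle Contrast with Inter-Frame Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form models for the temporal contrast of time-integrated
    laser speckle that account for correlation between consecutive frames,
    for Gaussian and Lorentzian field correlation functions, together with
    the combined spatio-temporal contrast for finite pixels and correlated
    sliding windows. Includes a quadrature oracle for the exposure-averaged
    correlation factors, a dynamic-speckle stack simulator with known ground
    truth, and the empirical pipeline used in laser speckle contrast imaging
    (LSCI): per-pixel temporal contrast maps, frame-correlation curves and
    decorrelation-time fitting, time history of the speckle pattern (THSP),
    exposure binning, and model fitting of contrast-versus-exposure curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
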