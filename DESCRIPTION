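Package: gaitforge
Title: Synthetic Gait Pattern Generation and Impedance-Control Training for
    Prosthetic Legs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates multichannel gait patterns (vertical load and thigh,
    knee and ankle angles) from coarse 11-node user sketches with a conditional
    generative adversarial network, converts patterns into 5-ms time series
    with aligned normalized impedance profiles, and trains neural networks
    that predict impedance-control parameters (equilibrium angles, stiffness,
    damping) for a powered prosthetic knee and ankle. Includes gait-cycle
    segmentation by smoothed z-score peak detection, median pattern
    extraction, a parametric synthetic benchmark-corpus generator, and
    evaluation metrics (R-squared, RMSE, one-dimensional structural
    similarity, boundary discontinuity, RMS jerk).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
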