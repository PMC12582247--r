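Package: stablegait
Title: Inference of Feedforward-Feedback Foot Placement Control from
    Locomotor Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recovering the control structure underlying stable
    legged locomotion from planar body and foot marker trajectories.
    Implements gait cycle segmentation and phase normalization,
    velocity-dependent nominal gait models (linear step length and width,
    exponential step duration), phase-resolved linear maps from body state
    errors to corrective foot placements with a foot-kinematics baseline,
    Poincare return-map stability, control magnitude and exponential decay
    timescales of lateral placement correlations, direction- and
    limb-specific feedback gains, Chatterjee's xi rank correlation, and a
    stochastic multi-legged walker simulator with known feedforward
    coefficients and feedback gains that provides ground truth for every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
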