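Package: astigTrack
Title: Simulation and Analysis of 3D Single-Molecule Feedback Tracking with
    Astigmatic Detection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for image-based three-dimensional single-particle tracking
    with astigmatic point-spread-function detection. Provides a synthetic
    image and trajectory simulator (elliptical-Gaussian PSF rendering, EMCCD
    noise, Brownian and two-state mobility models), template-based axial
    localization by normalized cross-correlation with a linear calibration
    metric, a simulated closed axial feedback loop, post-processing particle
    detection and nearest-neighbor trajectory linking, diffusion analysis by
    mean-square-displacement and cumulative jump-distance distribution
    mixture fitting (including global fits with shared diffusion
    coefficients), and exact Bernoulli run-length statistics for detecting
    significant dwell times and mobility-state transitions in single
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
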