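Package: kymotracer
Title: Automated Particle Track Extraction from Kymographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated tracing of particle trajectories in kymographs
    (space-time images in which rows are movie frames and columns are
    positions along a stationary path). Provides seeded simulators for
    unidirectional and bidirectional particle movies with ground-truth
    tracks, signal gaps and calibrated signal-to-noise ratios; a small
    convolutional (U-Net style) framework used to train classification,
    segmentation and branch-point decision modules on the simulated data;
    morphological skeleton tracing that turns per-pixel trackness maps into
    individual tracks; a stationary-wavelet baseline tracer; track-level
    recall/precision/F1, gap-bridging and crossing-resolution benchmarks;
    and per-track kinematic summaries (speed, directionality, pausing,
    reversals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Rcpp,
    EBImage,
    tiff,
    png,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
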