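Package: calciumvr
Title: Calcium Imaging and Behavioral Analysis for Immersive
    Virtual-Reality Visual Learning Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis of fast visual learning experiments in
    head-fixed mice combining an immersive virtual-reality corridor task
    with three-dimensional chessboard-scan two-photon calcium imaging.
    Provides a synthetic-data generator with full ground truth
    (trial-structured sessions, treadmill velocity, population calcium
    transients, chessboard movies), a fluorescence pipeline (per-subfield
    rigid motion correction with subpixel refinement, pixel-level mask
    cleaning, neuropil decontamination, percentile-baseline dF/F), a
    dynamic-time-warping bootstrap statistic for behavioral learning,
    abyss-test velocity-ratio metrics, ramp-amplitude and assembly/hub-cell
    analyses, a few-cell trial decoder, non-negative canonical polyadic
    tensor decomposition via block principal pivoting, and a Brown-Conrady
    radial lens distortion model for head-mounted-display optics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    minpack.lm,
    jsonlite,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
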