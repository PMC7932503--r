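Package: bariTrack
Title: Brachial Artery Wall Tracking and Relaxation-Index Analysis for
    B-Mode Cine Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tracks anterior and posterior lumen-wall positions in B-mode
    cine ultrasound of the brachial artery with a distance-regularized
    level-set evolution seeded from a user rectangle, builds the diameter
    surface D(x,t), partitions each cardiac cycle into systolic dilatation
    and diastolic relaxation windows, fits mono- and bi-exponential
    viscoelastic decay models by Nelder-Mead least squares, and aggregates
    the slow relaxation time constants into the brachial artery relaxation
    index (BARI). Includes cohort-level group comparisons and growth-rate
    statistics for abdominal aortic aneurysm surveillance data, and a
    ground-truthed synthetic speckle phantom generator (pulsating two-wall
    vessel in Rayleigh speckle) so that every stage of the pipeline can be
    validated without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    jsonlite,
    readxl,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
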