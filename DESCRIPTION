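Package: windeeg
Title: Decoding the Pleasantness of Wind from EEG Source Band Power
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested, fully synthetic re-implementation of an EEG decoding
    pipeline for the instantaneous pleasantness of wind. Provides a
    synthetic-experiment generator (spherical three-shell head model,
    octahedron-subdivision cortical source spaces, surrogate 68-region
    parcellation, trial schedules and visual-analog pleasantness reports),
    EEGLAB-style preprocessing (zero-phase band-pass filtering, epoching,
    robust bad-channel detection with spherical-spline interpolation,
    peak-to-peak artifact rejection, average re-referencing), an eLORETA
    weighted minimum-norm inverse solver with baseline noise covariance,
    Welch band-power feature extraction over frontal regions of interest,
    a confound-controlled leave-one-velocity-out classification protocol
    (undersampling with repetitions, training-only normalization, seeded
    hyperparameter search, four classifier families), band-ablation feature
    importance, and the group-level statistical battery (one-tailed
    one-sample t-tests with Holm correction, repeated-measures ANOVA with
    Greenhouse-Geisser correction).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    e1071,
    glmnet,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
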