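Package: motorlab
Title: Movement Kinematics, Posturography and 1D Statistical Parametric
    Mapping for Real-Versus-Virtual Motor Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for self-paced aiming
    movements (golf putting) recorded with a clubhead inertial measurement
    unit and a centre-of-pressure plate, compared across real-world and
    virtual-reality task conditions.  Provides swing segmentation and
    per-putt kinematic metrics (impact accelerations, sagittal variance,
    jerk), posturographic outcomes (RMS sway, sample entropy, path
    length, 95% prediction ellipse area), one-dimensional statistical
    parametric mapping with random-field-theory cluster inference over
    time-normalized swing continua, and linear mixed-effects condition
    contrasts with marginal and conditional R-squared.  A synthetic study
    generator with recorded ground truth makes every stage testable
    without access to laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    emmeans,
    jsonlite,
    lme4,
    lmerTest,
    Matrix,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
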