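Package: fingertap
Title: Accelerometer-Based Scoring of the MDS-UPDRS Finger-Tapping Task
Version: 0.1.0
Authors@R: person("Movere", "Analytics", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify bradykinesia from triaxial finger-worn
    accelerometer recordings of the MDS-UPDRS finger-tapping task. The
    pipeline epochs a raw 167 Hz trace into the first ten tap-to-tap
    movements using the level-1 Daubechies (db4) wavelet detail, extracts
    eighteen movement features (frequency, opening angle, hesitations,
    halts, hypometria, opening and closing accelerations and their trends),
    predicts the clinical 0-3 score with a proportional-odds cumulative
    logit model plus a low-variance rule for score 4, selects features by a
    greedy backward wrapper maximizing the Goodman-Kruskal Gamma under
    leave-one-out cross-validation, and evaluates with nested LOOCV,
    ordinal association, and ROC-based binary metrics. A parametric signal
    simulator generates severity-graded synthetic recordings so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
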