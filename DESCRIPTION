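Package: mibci
Title: Motor-Imagery EEG Classification with Common Spatial Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for three-class same-limb motor-imagery
    electroencephalography (EEG) analysis: seeded synthetic data generation
    emulating a cue-based imagery paradigm with planted mu/beta event-related
    desynchronization, preprocessing (downsampling, zero-phase Butterworth
    band-pass filtering, cue-locked epoching), feature extraction by common
    spatial patterns (CSP), filter-bank CSP, and logarithmic band power,
    one-vs-one multiclass classification (LDA, regularized logistic
    regression, RBF-kernel SVM with grid search) under repeated stratified
    cross-validation, and neurophysiological analyses (ERD/ERS time courses
    and R-squared topographic class-difference maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    glmnet,
    graphics,
    grDevices,
    MASS,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
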