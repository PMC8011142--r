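Package: ethoclass
Title: Behaviour Classification from Triaxial Accelerometer Data with
    Compact On-Board Model Export
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns raw triaxial accelerometer (ACC) streams into behaviour
    classifications for movement-ecology and biologging studies. Provides
    fixed-length bout segmentation with single-behaviour pruning, a
    78-feature summary-statistic catalogue plus simplified
    placement-specific feature sets (including ODBA, posture angles and
    spectral features), training and stratified 10-fold cross-validation
    of six supervised classifiers (LDA, decision tree, radial-kernel SVM,
    random forest, single-hidden-layer neural network and gradient-boosted
    trees), and export of trained SVM/ANN/RF/boosted-tree models to
    compact parameter structures with dependency-free inference engines
    suitable for transcription to microcontroller firmware, together with
    storage, compression-ratio and deployment-duration accounting. A
    synthetic labelled-signal generator with behaviour-specific posture,
    oscillation and noise supports testing and benchmarking without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    rpart,
    e1071,
    nnet,
    randomForest,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
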