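Package: markerless
Title: Markerless Motion Capture to Musculoskeletal Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale pipeline from multi-camera 2D video keypoints to
    musculoskeletal dynamics. Covers pinhole camera geometry and single-image
    checkerboard extrinsic calibration, cross-correlation video
    synchronization, confidence-weighted DLT triangulation, anatomical
    marker-set augmentation by trainable sequence regression, articulated-model
    scaling and inverse kinematics, Hill-type muscle and smooth compliant
    contact mechanics, inverse dynamics, muscle-driven tracking simulation by
    direct collocation, and the downstream clinical metrics and statistics
    (symmetry indices, ROC classification, paired-comparison batteries). A
    synthetic acquisition rig generates ground-truth cohorts so every stage is
    testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    signal,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
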