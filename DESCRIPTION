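Package: rigcheck
Title: Validation of Multi-Camera 3D Animal-Pose Capture Rigs with Rigid Test Objects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for validating multi-camera markerless 3D pose-capture
    arenas using rigid test objects of known geometry. Implements a pinhole
    camera model with radial-tangential distortion, multi-view DLT
    triangulation with reprojection refinement, camera resectioning and rig
    refinement from point correspondences, a parametric model of a rigid
    XYZ calibration object, a seeded simulator for surround-view camera
    rigs and rigid-object trajectories with detector-like pixel noise and
    dropout, and the validation statistics used to grade a rig:
    inter-keypoint distance error, deviation from a full-rig reference,
    bias/variance decomposition, quartile/whisker summaries, error versus
    image-centre Spearman correlation, and a two-way camera-configuration
    ANOVA with Tukey post hoc comparisons. Reads and writes Anipose-dialect
    calibration TOML and DeepLabCut-style detection CSV files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
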