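Package: footkin
Title: Multi-Segment Foot Model Kinematics for Gait Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A kinematics engine for a modified multi-segment foot model
    aimed at functional assessment of the flexible flat foot (pes planus).
    From stereophotogrammetric marker trajectories it computes static
    calibration products (including a heel-marker-based frontal-plane
    offset of the calcaneus relative to the shank), five three-dimensional
    joint rotations by the Grood-Suntay joint coordinate system, eight
    planar angles including a ground-referenced medial longitudinal arch
    angle, gait-cycle segmentation with time normalization and ensemble
    statistics, and hindfoot alignment classification. A forward-kinematics
    simulator generates marker trajectories with known ground truth for
    validation. Reads and writes C3D and a plain tab-separated trajectory
    format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    grDevices,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
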