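Package: haa3d
Title: Three-Dimensional Hindfoot Alignment Angle Measurement from Bone
    Surface Meshes
Version: 0.1.0
Authors@R:
    person("haa3d", "developers", email = "haa3d@example.org", role = c("aut", "cre"))
Description: Computes the hindfoot alignment angle (HAA), the frontal-plane
    varus/valgus inclination of the hindfoot relative to the tibia, from
    segmented bone surface meshes such as those reconstructed from
    weight-bearing cone-beam CT. Implements six measurement techniques based
    on surface principal component analysis of the calcaneus, talo-calcaneal
    axes, frontal silhouette contours, and posterior-tuberosity box clipping,
    within a ground-plane-anchored whole-foot anatomical frame. Includes a
    deterministic synthetic foot phantom generator with analytically known
    angles for validation, a pre/post-treatment cohort simulator, paired
    t-test summary statistics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
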