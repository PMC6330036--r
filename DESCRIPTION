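Package: boneqct
Title: Density-Weighted Moment Morphometry of Vertebral CT Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates longitudinal calibrated micro-CT studies of growing rat
    lumbar vertebrae as elliptical-shell density phantoms, segments cortical
    and cancellous bone, and computes volumetric bone mineral density, mean
    cortical thickness, vertebral body dimensions, and the density-weighted
    minimum cross-sectional and polar moments of inertia used as macroscopic
    bone-quality indices. Includes the two-group time-course comparison
    (pooled-variance Student's t per imaging day) and an end-to-end phantom
    study emulating a fasting intervention in which bone density recovers
    while the moment indices do not.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
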