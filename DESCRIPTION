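Package: handmotion
Title: Hand Motion Capture Kinematics: Cardan Joint Angles, BVH and
    Musculoskeletal Joint-Driver Export
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts per-frame hand-bone orientation bases (elbow to
    fingertips, as produced by marker-less optical hand trackers) into
    per-joint Cardan angle time series measured against a neutral-zero
    reference posture.  Exports the motion as Biovision Hierarchy (BVH)
    files and as joint-driver vector files suitable for B-spline driven
    inverse-dynamics simulation, extracts finger segment lengths for model
    scaling, and validates basis-derived angles against angles computed
    from 2D tracked marker positions.  A forward-kinematics synthetic
    generator with known ground-truth trajectories stands in for the
    hardware sensor.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
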