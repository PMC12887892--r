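Package: stepmetrics
Title: Video-Based Footstep Detection and Cognitive-Motor Speed Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement pipeline for floor-target psychomotor assessments
    captured on video. Calibrates a 3x3 layout of circular floor targets in
    image space (planar homography plus nine zone polygons, automatic with a
    semiautomatic fallback), smooths per-frame foot-landmark streams from any
    pose backend, declares stable ground-contact (step) events with joint
    displacement/stability/compactness heuristics, grounds contacts to target
    zones by footprint-polygon overlap, segments stimulus-locked trials into
    visuomotor reaction speed, displacement speed, response capacity and a
    composite cognitive-motor speed index, and runs the corresponding
    two-group comparison statistics (Student t, Mann-Whitney U with exact
    enumeration, Bonferroni adjustment, Cohen's d and r effect sizes,
    parametric and bootstrap confidence intervals). A fully synthetic session
    simulator with known ground-truth events makes every stage testable
    without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    pracma,
    png,
    EBImage,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
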