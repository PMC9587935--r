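Package: soundloc3d
Title: Analysis of 3D Sound Localization Experiments with Static and Active Listening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing three-dimensional sound-localization experiments in
    which a tracked loudspeaker is placed at predetermined head-centered positions and
    listeners point to the perceived sound location, either holding the head still
    (static listening) or moving it freely during sound emission (active listening).
    Provides head-center calibration and world-to-head-frame re-referencing of
    motion-capture data, offline re-implementation of the sound-delivery gating
    criteria, zero-phase FIR filtering and velocity-threshold movement segmentation,
    per-dimension (azimuth, elevation, depth) and composite 3D localization-error
    statistics, repeated-measures ANOVA with Greenhouse-Geisser correction and
    generalized eta squared, Holm-adjusted planned contrasts and Kendall rank
    correlation, plus a seeded generator of complete synthetic experiments with the
    study design's structure for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
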