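Package: pigtrack
Title: Observation-Centric Multi-Object Tracking and Behaviour Time
    Budgets for Group-Housed Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracking-by-detection for overhead video of group-housed pigs,
    without the detector: a constant-velocity Kalman filter on a
    seven-dimensional bounding-box state, data association combining
    intersection-over-union with a trajectory direction-consistency cost,
    observation-centric recovery of lost tracks and re-update along virtual
    trajectories across occlusion gaps, per-animal behaviour time accounting
    over the four classes lie/stand/eat/other, and HOTA/MOTA/IDF1 evaluation.
    Includes a synthetic pen simulator producing ground-truth scenes and
    degraded detection streams in a MOTChallenge-style text dialect, and a
    command-line interface with simulate, track, analyze-behavior and
    evaluate subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
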