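Package: palpmetrics
Title: Sensor-Based Quantification of Vascular Palpation Skill
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing multimodal sensor recordings of vascular
    palpation on a hemodialysis cannulation simulator. The package reads
    per-trial force, fingertip-position, needle-position and flashback
    channels, resamples them onto a common clock, isolates the palpation
    phase of each trial, and computes twelve time, force and location
    metrics (touchpoint counts, dwell and idle time, total force, force
    range, path length, ratio of correct movement, ratio of near
    touchpoints, and per-touchpoint dwell, force and distance to the
    anastomosis). Group comparisons (Mann-Whitney), success-probability
    estimates with Wilson intervals, stratified univariate logistic
    outcome models and Hill-curve summaries relate the metrics to skill
    level and cannulation outcome. A synthetic cohort generator with full
    ground truth emulates high-, mid- and low-performer behaviour for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
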