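Package: roboteye
Title: Synthetic Robotic-Eye Evaluation of Video-Based Eye Trackers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A digital twin of a stepper-motor-driven artificial eye for
    evaluating video-based eye trackers. Simulates 1000 Hz gaze-sample
    streams from a two-axis gimbal executing saccade patterns under
    different screen-brightness conditions, then runs the standard
    analysis chain on them: Savitzky-Golay velocity estimation, adaptive
    velocity-outlier saccade detection, fixation-based accuracy and
    precision metrology, main-sequence peak-velocity regression, and
    repeated-measures ANOVA with Mauchly sphericity diagnostics and
    Greenhouse-Geisser/Huynh-Feldt corrections, including the
    gaze-direction dependence of apparent pupil area.
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
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
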