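Package: drtask
Title: Simulation and Analysis of a Delayed-Response Joystick Task with
    Optogenetic Inactivation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete-event implementation of a two-alternative delayed-response
    joystick task for head-fixed mice: the trial state machine with anti-bias
    trial sequencing and adaptive staircase training, a parametric synthetic
    mouse emitting joystick traces, licks and laser schedules under optogenetic
    inactivation conditions, kinematic feature extraction (zero-phase
    Butterworth filtering, amplitude/speed/onset), signal-detection performance
    metrics (clamped d-prime, proportion answered, bias), the inferential layer
    (distributional gates, Kruskal-Wallis with Fisher LSD or Tukey-Kramer
    post-hoc on ranks, difference-in-differences regression with Huber robust
    fallback), and a laser-power calibration module for simulated spike trains.
    All inputs are synthetic; generators are first-class, tested code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    nortest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
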