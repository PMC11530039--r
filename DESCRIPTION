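Package: gaitphase
Title: Unsupervised Real-Time Continuous Gait-Phase Detection from Ankle Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a continuous gait phase from planar ankle marker
    trajectories without event labels. Windowed, standardized ankle
    positions and their heading directions are mapped by a small
    feed-forward network onto the unit circle; the network is trained by
    minimizing a four-term cost (phase-progression penalty, distribution
    term, singularity and marginal-singularity penalties) with analytic
    backpropagation. Includes a synthetic gait simulator with known
    ground-truth phase and heel-strike/toe-off events, kinematic event
    detection from horizontal ankle excursion, constant-reference-phase
    event recognition, time-error evaluation in milliseconds, and a
    subject-wise cross-validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
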