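Package: dualgate
Title: Dual Cardiac and Respiratory Gating from Chest-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for dual cardiac and respiratory gating of
    PET/CT acquisitions from a single chest-worn six-axis inertial measurement
    unit (tri-axial accelerometer and gyroscope). Fuses dorsoventral
    accelerations and superior-inferior angular velocities into one cardiac
    motion signal by independent component analysis, detects heartbeats with an
    automatic multiscale peak detector plus adaptive refinement, segments
    cardiac cycles and ejection times by short-time autocorrelation, and emits
    systolic/diastolic gating bins. Extracts five chest-inclination respiration
    channels from gravity projections and integrated angular rates, fuses them
    by principal component analysis, and emits peak-inhalation triggers and
    respiratory gating bins. Includes a seeded synthetic chest-motion simulator
    with ground truth, evaluation metrics (sensitivity, precision, F1, RMSE,
    heart rate, cardiac cycle percentage, trigger offsets), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
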