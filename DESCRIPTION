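Package: legmov
Title: Full-Day Infant Leg Movement Detection from Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and counts infant leg movements in full-day recordings
    from bilateral ankle-worn inertial measurement units (tri-axial
    accelerometer and gyroscope at 20 Hz). Implements per-recording adaptive
    acceleration thresholds calibrated from the statistics of band-limited
    signal peaks, a zero-crossing movement segmentation rule that requires
    concurrent rotation (rejecting background motion from cars, strollers and
    swings), awake-time movement-rate normalization against a parent activity
    log, validation scoring against observer counts, a synthetic six-channel
    IMU generator with ground-truth events, and a heteroscedastic
    repeated-measures model relating movement rate to walking-onset age.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
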