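Package: headconform
Title: Head-Motion Conformity Analysis for Passive VR Driving Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing head-tracking telemetry recorded while
    observers watch pre-recorded driving laps in a virtual-reality headset.
    Reads per-trial head-rotation logs (pitch/yaw/roll at ~90 Hz), vehicle
    yaw traces, and per-trial self-report tables (vection, motion sickness,
    presence on 1-20 scales); preprocesses traces (unwrap, centre, uniform
    resampling); computes mean absolute angular velocity, each participant's
    conformity to the leave-one-out median head trajectory, and the
    cross-correlation lag between head and vehicle yaw (negative lags mark
    anticipatory head turns). Includes within-subjects factorial ANOVA with
    partial eta squared, conformity-rating association tables, counterbalanced
    schedule enumeration for the two study designs, and a seeded synthetic
    cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
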