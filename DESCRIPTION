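Package: frailwear
Title: Wearable Fall Detection, Exercise Repetition Counting and
    Respiratory Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing toolkit for a body-worn sensing platform
    aimed at frail and pre-frail adults: two-stage accelerometry-based
    fall detection (on-device impact triggering followed by gateway-side
    posture and vertical-displacement classification), sawtooth
    parameterization of exercise accelerometry for activity
    discrimination, repetition counting and metabolic-expenditure
    estimation, respiratory-cycle segmentation with motion-artifact
    gating, and the gateway alert/personalization logic. Includes a
    deterministic synthetic-signal generator replicating the laboratory
    validation protocol (activities of daily living, simulated falls,
    static maintenance exercises, walking, cycling and a controlled
    breathing ramp) so every stage is testable without recorded data.
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
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
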