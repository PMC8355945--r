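Package: sonarwing
Title: Call-Wingbeat Coupling Analysis for Echolocating Bat Biologging Tags
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sound-and-movement biologging tag data from
    echolocating bats: ground-truthed synthetic tag recordings (accelerometer,
    ultrasonic audio and truth tables), wingbeat-cycle and wingbeat-phase
    extraction from heave accelerometry, echolocation call detection and
    source-level calibration in energy flux density, rule-based behavioural
    segmentation into commute, search, approach and buzz phases, per-wingbeat
    vocal-locomotor coupling metrics, and cross-species sensory-update-rate
    arithmetic. All user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
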