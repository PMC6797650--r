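Package: contactvalid
Title: Validation of Proximity-Sensor Face-to-Face Contact Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing the construct and criterion validity of
    face-to-face interaction data collected with wearable proximity sensors
    (RFID badges). Provides a tidy event-log representation of dyadic contact
    intervals, the three standard cleaning strategies for flickering sensor
    signals (minimal-duration filtering, gap interpolation, and iterated
    triadic closure), dyad-second confusion-matrix validation against
    ground-truth codings (sensitivity, specificity, accuracy, Cohen's kappa),
    cutoff sweeps, aggregation to weighted contact matrices, and logistic
    models relating contact durations to self-reported interaction
    nominations. A seeded synthetic-data generator produces paired
    ground-truth and sensor-observed contact logs with known flicker,
    group-detection, and self-report parameters for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
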