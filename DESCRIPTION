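Package: actimets
Title: Activity Counts, MET Prediction and Between-Device Reliability for
    Raw Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Turns raw tri-axial accelerometer recordings into ActiGraph-style
    activity counts, estimates energy expenditure in metabolic equivalents
    (METs) with five published prediction equations and their
    Harris-Benedict-corrected forms, classifies activity intensity, and
    quantifies between-device and between-placement reliability with
    standardized Cronbach's alpha and two-way mixed intraclass correlation
    coefficients. Includes a seeded synthetic gait-signal generator that
    emulates a paired-device, multi-speed treadmill protocol so the complete
    pipeline can be exercised and validated without access to recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
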