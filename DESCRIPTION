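Package: paqcal
Title: Calibrating the Physical Activity Questionnaire Against Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating Physical Activity Questionnaire (PAQ-C and
    PAQ-A) summary scores against accelerometer-measured moderate-to-vigorous
    physical activity (MVPA) in youth. Screens 30-second epoch activity-count
    data with wear-time and valid-day rules (8 a.m. to 9 p.m. day window,
    90-minute zero-count non-wear bouts with a low-count allowance, age-specific
    MET-based cut points), scores PAQ item responses, fits and cross-validates a
    linear calibration model mapping PAQ score, age and sex to percent time in
    MVPA, converts predictions to weekly MVPA minutes, and evaluates agreement
    with Bland-Altman limits, paired tests and guideline-classification
    statistics. A synthetic-cohort generator reproduces the statistical
    structure the analysis assumes so the full pipeline is testable without
    external data.
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
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    jsonlite,
    lmtest,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
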