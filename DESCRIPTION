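Package: officeactivity
Title: Office Worker Activity and Space-Utilization Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processes worn-accelerometer 60-second MET epoch series into
    sedentary-behavior and physical-activity summaries (non-wear detection,
    valid-day filtering, prolonged sedentary bouts, working-hours windowing
    and normalization), aggregates person-detection logs over labelled office
    floor-plan zones into 15-minute occupancy counts, and analyses both with
    split-plot (mixed) repeated-measures ANOVA including a covariate-adjusted
    variant and Bonferroni post hoc contrasts. Ships seeded synthetic-data
    generators for epoch series, entry/exit logs, floor plans and detection
    logs so the full pipeline is reproducible without access to raw study
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    jsonlite,
    pracma,
    withr,
    ggplot2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
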