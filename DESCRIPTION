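Package: gazechar
Title: Eye-Gaze Characterization and Mental-Workload Metrics for
    Screen-Based Assistive Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates screen-based eye-gaze characterization tasks
    (free-viewing "painting", dwell-to-select focus targets, smooth-pursuit
    tracking) together with the physiological signals they elicit (gaze,
    pupil diameter, RR intervals), detects eye-movement events with an
    adaptive velocity-threshold classifier, and computes task metrics
    (screen-coverage displacement, dwell success versus target size,
    pursuit statistics) and mental-workload metrics (change in pupil
    diameter, heart rate, ultra-short-term RMSSD) both per task and in
    rolling windows. Workload metrics are compared with intraclass
    correlation, Bland-Altman limits of agreement, and Sakoe-Chiba-banded
    dynamic time warping.
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
    minpack.lm,
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
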