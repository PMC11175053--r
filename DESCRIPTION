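Package: cmpl
Title: Cleaned Meta Pseudo Labels for Wearable-Sensor Behavior Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Semi-supervised training of behavior classifiers on windowed
    multi-sensor (IMU) time series with cleaned meta pseudo labels: a
    teacher-student meta pseudo labels loop, unsupervised-data-augmentation
    (UDA) consistency training with time-series augmentations, and
    embedding-centroid distance-based detection and relabeling of inactive
    (noise) windows contaminating the unlabeled pool. Includes a synthetic
    wearable-sensor data generator with class-specific motion signatures,
    inactive contamination and transmission-loss missing values, so the whole
    pipeline is testable end to end, plus metrics and a desk-scale
    ablation/benchmark harness.
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
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    class,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
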