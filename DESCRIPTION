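Package: breathgc
Title: Breath-Phase GC-MS Chromatogram Processing and Exposure-Group Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for exhaled-breath GC-MS total-ion
    chromatograms: import of instrument text exports, topographic
    prominence/width peak detection with per-peak feature extraction
    (retention time, height, prominence, width at relative height, chord-
    subtracted area), moving-average low-pass filtering, robust signal-to-
    noise quality control, and per-condition mean-signal comparison across
    pre-exposure, immediately-post-exposure and two-hours-post-exposure
    breath samples, with windowed intensity summaries in the early, mid and
    late retention ranges. Includes a seeded synthetic chromatogram and
    cohort generator with full ground truth for validating detection and
    group-effect recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
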