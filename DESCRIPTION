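Package: ecgpsr
Title: ECG Biometric Identification from Phase-Space Portraits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-beat electrocardiogram (ECG) biometrics via time-delay
    phase-space reconstruction. Filters raw single-lead ECG, detects and
    verifies QRS fiducials, cuts single-cycle beats, embeds each beat into a
    two-dimensional phase space with a configurable time delay, rasterizes
    the trajectory over an r-by-r occupancy grid into a binary phase
    portrait, and identifies individuals with a convolutional network
    trained on the portraits. Includes a multi-subject synthetic ECG
    generator with per-subject P/QRS/T morphology and beat-to-beat
    variability, two reference network architectures with exact shape
    propagation and parameter counting, and a factorial sweep over time
    delay and grid density with stage-averaged accuracy reporting.
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
    png,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
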