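Package: linebp
Title: Continuous Brachial Blood Pressure Estimation from Dialysis Line Pressures
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for continuous, non-invasive estimation of brachial mean
    arterial pressure (MAP) during haemodialysis from pressure sensors on the
    extracorporeal arterial and venous blood lines. Implements sliding-window
    Fourier estimation of the peristaltic blood-pump frequency and its
    conversion to blood flow, calibration of a Bernoulli lumped parameter
    against intermittent arm-cuff readings, continuous MAP reconstruction from
    the filtered arterial-line pressure, per-needle-gauge calibration
    summaries, and pooled versus per-session-compensated regression analyses.
    Includes a synthetic dialysis-session generator with known ground truth
    for validating every stage of the pipeline, CSV/YAML session I/O, ggplot2
    visualisations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
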