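Package: temposample
Title: Random Temporal Sampling Simulation and Classification-Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for the random temporal sampling paradigm in visual
    psychophysics. Simulates spatially band-pass filtered word stimuli whose
    signal-to-noise ratio oscillates randomly over a 200 ms display, runs a
    synthetic four-alternative forced-choice experiment under an adaptive
    contrast staircase, and recovers time-domain and time-frequency
    classification images from the trial logs. Classification images are
    z-scored by bootstrap, smoothed, and thresholded with a max-statistic
    Pixel test; individual images are recoded into time, Fourier, and
    time-frequency feature spaces and classified by spatial-frequency
    condition with a stepwise, leave-one-out linear support vector machine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
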