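Package: gazesearch
Title: Eye-Movement Analysis of Visual Search for Spatial-Frequency-Defined Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how searchers adjust their eye-movement
    dynamics to the spatial-frequency content of a search target in natural
    scenes. Synthesizes Gaussian-blob, difference-of-Gaussians and Gabor
    targets and embeds them into calibrated luminance images; detects
    saccades in raw gaze traces with a velocity-based, median-standard-
    deviation threshold algorithm and derives filtered fixation sequences;
    computes scanpath-dynamics statistics (saccade amplitudes, fixation
    durations, ordinal time-courses, intersaccadic-angle analyses);
    estimates empirical fixation-density maps by kernel density estimation
    with leave-one-subject-out cross-validated bandwidth and scores
    fixations by log-likelihood against a uniform baseline; and compares
    amplitude spectra of fixated versus control image patches. A synthetic
    scanpath and stimulus generator with known ground truth supports
    end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
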