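Package: cagesleep
Title: Video Actigraphy Sleep/Wake Staging for Mouse Home-Cage Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Noninvasive sleep/wake staging of mice from infrared home-cage
    video. Detects the animal in each frame (Gaussian smoothing, adaptive and
    global thresholding, connected components, a trainable mouse-versus-
    background patch classifier), converts windowed frame-difference features
    (prediction score, mask overlap, centroid displacement, mean gray) into a
    per-second activity trace, and scores sleep as sustained immobility
    (>= 40 s) with a movement-merging filter that relabels brief (<= 15 s)
    movements between two sleep bouts as sleep. Includes a synthetic home-cage
    simulator with known ground truth (semi-Markov sleep/wake bouts, sleep
    twitches, light/dark phases, static distractors), epoch-by-epoch agreement
    metrics against reference hypnograms, hourly sleep-time summaries, NREM
    delta-power and state-wise EEG spectra analytics from per-epoch band-power
    tables, and wake-to-REM (narcolepsy-like) episode detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
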