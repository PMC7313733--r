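Package: boxfd
Title: Box-Counting and Generalized Fractal Dimensions for Physiological Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Complexity analysis of multi-channel physiological recordings
    (EEG, facial EMG) via the box-counting fractal dimension of the signal
    graph and generalized (Renyi) dimensions of an amplitude-occupancy
    measure.  Includes Butterworth band-pass preprocessing, a synthetic
    study generator based on fractional Brownian motion with analytically
    known graph dimension (D = 2 - H), repeated-measures inference across
    stimuli, questionnaire scoring, and an end-to-end study pipeline that
    emits per-stimulus fractal-dimension tables and test statistics for
    within-subject 2D versus 3D viewing designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
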