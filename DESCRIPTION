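Package: segbeat
Title: Heartbeat Classification with Rhythm-Context Segment Labels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inter-patient heartbeat classification for annotated ECG
    recordings. Computes per-beat RR-interval, medical-morphology and
    mathematical-morphology features (five-part moments, Daubechies-2
    wavelet coefficients, Hermite basis-function expansions), selects
    features by a k-nearest-neighbour mutual-information estimator, and
    augments them with a novel rhythm-context feature: the rhythm class
    predicted for the surrounding ECG segment by a pluggable segment
    classifier (a built-in trainable 1-D convolutional network or a
    ground-truth oracle for synthetic data). Beats are classified by a
    class-balanced random forest and evaluated under the AAMI five-class,
    inter-patient protocol with macro-F1 as the headline metric. Includes
    a synthetic ECG generator with exact ground-truth fiducial points and
    rhythm-dependent beat timing so the whole pipeline is testable
    without external data.
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
    ranger,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
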