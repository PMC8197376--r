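Package: anurapam
Title: Anuran Call Classification and Edge-Deployment Cost Modelling for
    Passive Acoustic Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for classifying anuran (frog and
    toad) vocalizations in passive acoustic monitoring recordings: a
    seeded generator of synthetic calls for five vocalization classes of
    Epidalea calamita and Alytes obstetricans, waveform augmentation
    (white-noise injection, circular time shifts, dynamic-range
    compression), a 128-band x 435-frame log-mel spectrogram front end, a
    compact three-block convolutional network classifier with
    origin-grouped train/test splitting and confusion-matrix evaluation,
    and an analytic cost model comparing centralized (ship-the-audio)
    against distributed (ship-the-result) deployment of the classifier on
    low-bandwidth remote sensor nodes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jpeg,
    jsonlite,
    stats,
    utils,
    grDevices,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
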