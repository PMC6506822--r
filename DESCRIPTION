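Package: fearresp
Title: Multimodal Analysis of Respiration, Ultrasonic Vocalization and
    Brain Oscillations During Rodent Fear Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse multimodal recordings of rodent fear
    behaviour: detection of respiratory cycles from plethysmograph
    traces, automatic freezing scoring from video frame differences,
    detection and grouping of 22-kHz ultrasonic vocalizations (USV)
    from spectrogram whistle tracking, segmentation of post-shock
    windows into four behaviour-by-vocalization categories, continuous
    Morlet wavelet scalograms with per-category band power, joint
    histograms of instantaneous respiratory and dominant LFP frequency
    with a diagonal coupling index, and respiratory-phase-normalized
    ("cycle-frequency") scalograms quantifying phase modulation of
    beta and gamma amplitude. Includes a synthetic-session simulator
    with full ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
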