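Package: toposeize
Title: Topological Classification of Multichannel EEG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for classifying multichannel EEG recordings with
    topological data analysis. Builds sublevel-set (piecewise) filtrations
    of sampled signals and Vietoris-Rips filtrations of the sensor point
    cloud under a standardized Euclidean metric, computes persistence
    barcodes by union-find and by boundary-matrix reduction over GF(2)
    (with representative generators), summarises barcodes by persistent
    entropy, and trains a one-feature linear threshold classifier evaluated
    by ROC/AUC with a Sample Entropy baseline. Includes EDF and CSV signal
    input/output, band-pass/notch/decimation preprocessing, a seeded
    two-class synthetic recording generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    pROC,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
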