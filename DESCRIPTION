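Package: chaoseeg
Title: Encrypted EEG Spectrogram Classification with Chaotic Maps and a
    Compact Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and classification pipeline for seizure detection on
    encrypted electroencephalogram (EEG) spectrograms. Generates labelled
    synthetic EEG segments (interictal background, preictal rhythm, ictal
    3 Hz spike-wave discharges), transforms channels with the Teager-Kaiser
    energy operator into quantized time-frequency images, scrambles the
    images with discretized generalized baker and Arnold cat map permutation
    ciphers, and classifies them with an ensemble of compact convolutional
    networks whose soft-voting fusion weights are tuned by a hybrid
    crow/sparrow-style swarm optimizer. Includes stratified k-fold
    evaluation with accuracy, sensitivity, specificity, precision and F1,
    and Kruskal-Wallis comparison of methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    pracma,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
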