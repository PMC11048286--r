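Package: csteeg
Title: Convolutional Sparse Transformer for EEG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for classifying multichannel EEG directly from raw
    waveforms with a convolutional sparse transformer: a spatial channel
    attention gate over electrodes, equidistant-query sparse self-attention
    with mean-of-values fill for lazy positions, and distilling
    convolutional layers that halve the temporal dimension between encoder
    layers. Includes EDF/EDF+ reading, zero-phase Butterworth filtering,
    epoch segmentation, stratified and grouped data splits, a synthetic
    band-limited EEG generator with 1/f background noise, a full training
    and evaluation harness (holdout repeats, k-fold cross-validation,
    ablation switchboard, hyperparameter sensitivity sweeps), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
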