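Package: somnostage
Title: Automatic Sleep-Stage Classification from Multi-Taper Spectrogram Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline pipeline for automatic AASM five-stage sleep scoring
    from polysomnography. Reads EDF or delimited-text recordings (two EEG and
    two EOG channels), applies powerline notch and 0.3-35 Hz Butterworth
    band-pass filtering with interpolation-based resampling to 200 Hz, converts
    signals to multi-taper (DPSS) spectrograms, renders per-epoch four-channel
    spectrogram images, and classifies each 30-second epoch into W, N1, N2, N3
    or R with a convolutional network (or a CNN+LSTM on raw signals), trained
    with Adam, learning-rate annealing and early stopping. Includes Cohen's
    kappa and confusion-matrix evaluation, hypnogram export, and a synthetic
    polysomnography simulator with stage-dependent spectral content so the
    whole pipeline is testable without any external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    png,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
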