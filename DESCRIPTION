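Package: auscultnet
Title: Multi-Channel Lung-Sound Classification with a Residual CNN-LSTM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying adventitious respiratory sounds (normal,
    wheeze, fine crackle) from multi-channel chest auscultation recordings.
    Provides WAV input/output and resampling, a seeded synthetic multi-channel
    lung-sound simulator (breath envelopes, crackle transients, wheeze tones,
    ICU-style background contamination), an augmentation suite built around
    convex background-noise mixing, MFCC feature extraction with row-wise
    channel fusion, a from-scratch residual CNN-LSTM classifier trained with
    rectified Adam, a three-session ensemble training protocol, one-vs-rest
    evaluation metrics, channel-ablation experiments, and gradient-weighted
    class-activation maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
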