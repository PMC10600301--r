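Package: wavefusion
Title: Subject-Aware Contrastive Fusion Networks for Multi-Lead EEG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements a multi-lead EEG classification framework that fuses
    per-lead lightweight convolutional networks through a temperature-flattened
    squeeze-and-excite attention module. Representations are pretrained with a
    subject-aware contrastive loss that uses subject identity when forming
    positive and negative sets, then fine-tuned as a binary classifier.
    Includes a synthetic multi-subject EEG generator with controllable
    band-limited class effects, an STFT spectrogram preprocessing pipeline,
    training and ablation harnesses, and interpretability outputs (attention
    topomaps and class activation maps). All network forward and backward
    passes are implemented in vectorised base R.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
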