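Package: rsae
Title: Robust Stacked Autoencoders for Multichannel EEG Seizure Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segment-level epileptic seizure detection from multichannel
    EEG.  Each short window is summarised as a band-integrated cross-power
    spectral matrix; the most discriminative frequency band (theta, alpha
    or beta) is chosen by Fisher's discriminant ratio on the training
    split; a stacked sparse autoencoder is pretrained on the scaled
    features and jointly fine-tuned with a softmax classifier.  The
    autoencoder reconstruction loss can be the classical mean square error
    or the maximum correntropy criterion, whose bounded influence function
    suppresses the impulsive outliers that EMG artifacts leave in the
    cross-power domain.  Includes a synthetic multichannel EEG generator
    (pink-noise background, coherent band-limited seizure oscillations,
    label-independent EMG-like bursts), delimited-text and 16-bit EDF
    recording I/O, Welch cross-spectral estimation, deterministic
    full-batch training, and an evaluation pipeline reporting
    sensitivity and specificity over repeated trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
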