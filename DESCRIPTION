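Package: mitransfer
Title: Unsupervised Transfer Learning for Motor-Imagery EEG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Cross-subject transfer learning for two-class motor-imagery
    electroencephalography (EEG). Implements discrete-wavelet band denoising
    (db6), Euclidean-space data alignment of trial covariance matrices,
    common-spatial-pattern (CSP) spatial filtering with log-variance
    features, and a small two-dimensional convolutional network classifier,
    together with CSP+SVM and fine-tuning CNN baselines, a synthetic
    motor-imagery EEG generator with controllable between-subject domain
    shift, a plain-text trial container format, an end-to-end evaluation
    pipeline, and a t-SNE domain-shift diagnostic.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
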