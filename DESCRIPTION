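Package: affectkit
Title: Stress Classification and Continuous Emotion Regression from Physiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dual framework for affect recognition from wearable biosignals:
    a 1D convolutional network for stress classification with transfer-learning
    fine-tuning to activity recognition, and a Temporal Conformer (convolution +
    self-attention) regressor for continuous valence-arousal-dominance prediction
    from ECG. Includes a 33-feature extractor (statistical, Daubechies-4 wavelet,
    and short-time Fourier features), explainability tools (1D Grad-CAM,
    Integrated Gradients, attention maps, t-SNE of pooled embeddings), rule-based
    emotional-state diagnostics with fatigue and motion-quality indices, readers
    and writers for EDF signals, MAT v5 trial containers and CSV feature tables,
    and synthetic-data generators so every stage is trainable and testable
    without access to the original recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    data.table,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
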