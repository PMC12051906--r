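Package: seizalign
Title: Cross-Species EEG Seizure Detection by Multi-Space Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transfer learning for EEG-based seizure detection across
    heterogeneous recording domains (species, montages, sampling rates).
    Implements input-space Euclidean alignment (per-subject covariance
    whitening), a learnable linear channel projection that unifies montages
    of different sizes, feature-space domain adaptation (multi-kernel maximum
    mean discrepancy and minimum class confusion), and output-space knowledge
    distillation with temperature-scaled Kullback-Leibler divergence, all over
    a compact convolutional backbone trained end-to-end. Ships a synthetic
    two-domain epileptic EEG generator with shared latent seizure dynamics so
    the full pipeline is testable without external data, plus signal
    diagnostics (approximate entropy, PSD spectrograms) and AUC-based
    evaluation of unsupervised and semi-supervised transfer scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    Rcpp,
    ggplot2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
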