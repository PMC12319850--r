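Package: riemnet
Title: Deep Riemannian Networks for Multichannel EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end deep Riemannian networks for decoding multichannel
    EEG: learnable convolutional and sinc bandpass filterbanks feeding
    covariance (SCM) pooling and an SPDNet (BiMap/ReEig/LogEig layers with
    Stiefel-constrained weights trained by Riemannian Adam), plus a
    black-box-optimised filterbank variant scored by cross-validated
    Riemannian proxy classifiers (minimum distance to Riemannian mean and
    tangent-space SVM under affine-invariant or log-Euclidean metrics).
    Includes a synthetic band-power EEG generator, exact Wilcoxon
    signed-rank comparisons, and a post-hoc analysis toolkit (frequency
    gain spectra, multiband peak counting, layer-by-layer probing,
    eigenvalue threshold audits, BiMap gain maps, and gradient-based
    electrode-frequency relevance).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
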