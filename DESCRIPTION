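Package: histobias
Title: Planted-Bias Discovery in Histopathology CNNs with Concept and
    Saliency Explanations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A validation pipeline for bias discovery in histopathology
    patch classifiers. Generates synthetic two-class histology-like tile
    datasets with controlled, planted biases (class sampling ratio,
    measurement/source confound, sampling bias, class-correlated marker),
    trains a compact residual convolutional network with Swish activations
    on them, and applies two complementary explanation methods: automated
    concept extraction (multi-resolution SLIC superpixels clustered in the
    network's fully connected activation space) scored with concept
    activation vectors (TCAV), and Guided Grad-CAM saliency maps. Decision
    checks turn the explanations into operational bias flags (concept
    dominance shift, marker overlap, source purity) so that each planted
    bias can be shown to be recoverable from the explanations alone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
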