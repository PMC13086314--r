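Package: awpfnet
Title: Adaptive Window Pyramid Fusion Networks for Fine-Grained Mushroom
    Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements AWPF-ResNet18, a lightweight fine-grained image
    classifier for edible mushroom species. A truncated residual backbone
    (stem plus the first two residual stages, with a 1x1 channel adapter)
    feeds an Adaptive Window Pyramid Fusion module: a convolutional
    downsampling pyramid whose levels are refined by Dynamic Swin Window
    blocks - shifted-window self-attention with resolution-adaptive window
    sizes - and fused bottom-up by bilinear upsampling and element-wise
    addition. Includes a reverse-mode automatic-differentiation engine for
    training with AdamW, imbalance-aware macro metrics (macro precision,
    recall and F1 with per-class precision-recall curves), Grad-CAM visual
    explanations, a deterministic procedural generator of class-separable
    synthetic mushroom images, and a command-line interface for data
    generation, training, evaluation and explanation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    png,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    nnet,
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
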