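Package: cmrice
Title: Cross-Modal Image-Text Retrieval Toolkit for Rice Leaf Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale toolkit for dual-encoder cross-modal image-text
    retrieval of rice leaf diseases. Implements two-way mixed self-attention
    (TMS) feature enhancement, a Bayesian false-negative elimination (FNE)
    negative sampler combined with hard negative mining (HNM) inside a
    triplet ranking objective, a momentum memory bank of negative
    embeddings, a warm-up bat-algorithm (WBA) learning-rate schedule, and
    Recall at K evaluation. Ships tiny deterministic encoders and a
    synthetic image-caption world generator with planted false negatives so
    every component is verifiable on a single CPU without pretrained
    transformer backbones or the original field dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
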