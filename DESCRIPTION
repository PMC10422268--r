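Package: cropseg
Title: Attention-Augmented Encoder-Decoder Segmentation for Crop Mapping
Version: 0.1.0
Authors@R:
    person("cropseg", "developers", email = "cropseg@example.org", role = c("aut", "cre"))
Description: Semantic segmentation of multispectral reflectance imagery into
    crop classes (corn, soybean, other) with a SegNet-style encoder-decoder
    augmented by convolutional block attention (channel and spatial gates).
    Includes a synthetic field-mosaic generator with class-wise spectral
    signatures and mixed boundary pixels, an 8-channel feature stack builder
    (six raw bands plus NDVI and red-edge NDVI), spatial train/test splitting
    with random crop sampling and edge-ignoring test tiling/stitching, a
    CPU training loop (Adam, weight decay, early stopping), confusion-matrix
    metrics (overall accuracy, mean IoU, Cohen's kappa), 2-D feature
    embeddings with silhouette separability, and a cross-domain (simulated
    cross-year) transfer evaluation harness. The network, attention modules
    and backpropagation are implemented natively with RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    MASS
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
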