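Package: chromswarm
Title: Sequence-Free Enhancer Prediction from Chromatin Occupancy with
    Swarm-Based Model Interpretation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts enhancers from binned ChIP-seq occupancy alone, with no
    DNA sequence input. Builds labeled training sets from STARR-seq/ATAC-seq
    peak intersections over 1 kb genomic tiles, featurizes tag occupancy into
    [0,1]-normalized tensors at 10 bp resolution, and trains any of seven
    classifier architectures (DNN, 1D/2D CNN, LSTM hybrids, and a
    Kolmogorov-Arnold network) behind a single predictor contract. Trained
    predictors are interrogated three ways: adversarial particle swarm
    optimization (APSO), an architecture-agnostic attack that reconstructs the
    chromatin profiles driving inference (with an inverted-cost mode for
    anti-predictive features), plus integrated-gradients and saliency
    attribution for cross-validation. Includes a synthetic chromatin generator
    with planted signatures so the full pipeline is testable end to end, and
    downstream peak-enrichment and contact-ratio statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    splines,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet
Config/testthat/edition: 3
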