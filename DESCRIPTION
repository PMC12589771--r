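Package: staincast
Title: Single-Cell Spatial Gene Expression Prediction from H&E Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts nucleus-level spatial gene expression directly from
    hematoxylin-and-eosin histology. Aggregates 2-micron binned spatial
    transcriptomics counts into per-nucleus training labels, fuses local
    (nucleus-patch) and global (whole-tile) histology features per cell, and
    trains a dual-loss class-weighted feed-forward regressor that jointly
    predicts whether each gene is expressed and at what level. Ships a seeded
    synthetic-slide generator (H&E-like image, nucleus polygons, binned
    counts, ground truth) so the full pipeline runs and is testable at desk
    scale, plus per-gene Pearson correlation / RMSE evaluation and a
    local-versus-global feature ablation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    arrow,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    methods,
    purrr,
    rhdf5,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    mclust,
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
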