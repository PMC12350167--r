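Package: pixelplex
Title: Pixel-Level Protein Co-Expression Analysis for Cyclic Multiplexed
    Immunofluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for cyclic multiplexed immunofluorescence
    experiments imaged over many staining cycles. Aligns per-cycle images to a
    first-cycle reference by subpixel phase correlation (with optional
    keypoint-based projective refinement) and quality-controls alignments with
    structural-similarity flags; derives tissue foreground and erythrocyte
    masks; interpolates and subtracts per-wavelength autofluorescence from
    secondary-only cycles and quality-controls antibody elution; draws
    weighted stratified pixel subsamples; fits per-channel histogram clipping
    and range normalization; discovers pixel-level protein co-expression
    clusters with a batch self-organizing map followed by (batch-balanced)
    k-nearest-neighbour graph construction and Leiden community detection;
    quantifies cluster abundance, differential abundance and per-cluster
    marker contributors; summarizes spatial adjacency with queen-neighbourhood
    join counts and vicinity graphs; aggregates pixel clusters into cell-level
    metaclusters around externally segmented nuclei; and generates fully
    synthetic experiments with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    mclust,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
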