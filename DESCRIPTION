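Package: ciliometry
Title: 3D Cilium Segmentation, Skeleton Morphometry and Replicate-Aware
    Statistics for Fluorescence Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end, scriptable pipeline for quantifying primary
    cilia in multi-channel 3D fluorescence microscopy stacks. Provides
    histogram-based auto-thresholding (Otsu, Li, Yen, Renyi entropy,
    Moments, Minimum, Shanbhag) and hysteresis segmentation of a ciliary
    marker channel, connected-component object detection with size and
    border filtering, skeleton-based per-cilium morphometry (tree length,
    largest-shortest-path cilium length, branch count, bending ratio) on
    anisotropic voxel grids, and a downstream explorer stage that pools
    per-condition measurement tables, runs quality control, selects
    statistical tests through a Shapiro/Levene decision tree, computes
    PCA/UMAP/LDA on morphometric feature tables, and draws replicate-aware
    superplots. A phantom generator renders synthetic cilia with
    analytically known centerline arc lengths so the full pipeline is
    verifiable against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tools,
    igraph,
    MASS,
    car,
    tiff,
    EBImage,
    ggplot2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
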