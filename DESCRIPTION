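Package: cloudmorph
Title: Point-Cloud Morphometry of Single Cells in 3D Tissue Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A toolkit for landmark-free quantification of cellular
    architecture in membrane-labeled 3D fluorescence stacks. Provides
    channel bleed-through unmixing, automated 3D single-cell watershed
    segmentation, intensity-biased stochastic landmark assignment (ISLA)
    to convert voxel images into point clouds, tissue and cell frames of
    reference (TFOR/CFOR), cluster-based feature embedding (CBE) with a
    moments baseline, cross-channel atlas regression with support vector
    machines, morphological archetype classification, tissue consensus
    maps and correlation bigraphs. Ships a synthetic cell-shape generator
    with known latent parameters as a built-in validation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    grDevices,
    MASS,
    e1071,
    jsonlite,
    tiff,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
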