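Package: tensorPheno
Title: Tensor-Based Organ Segmentation and Morphological Phenotyping of
    3-D Plant Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments single-plant 3-D point clouds (multi-view-stereo
    reconstructions) into leaf- and stem-related points using per-point
    first- and second-order tensor analysis, detects stem nodes as
    high-lambda2 regions, and derives whole-plant morphology (height,
    width, voxel-occupancy volume with a five-cell noise filter) and
    internode lengths. Includes a labeled synthetic sunflower-like plant
    generator for end-to-end validation, thermal-time (growing degree
    day) conversion, three-parameter log-logistic attachment-dynamics
    fitting, and the group-comparison statistics (ANOVA, Tukey-HSD,
    accuracy regression) used in early broomrape-infection phenotyping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    tools,
    stats,
    grDevices,
    utils,
    igraph,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
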