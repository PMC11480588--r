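Package: PlantPointSeg
Title: Stem-Leaf Segmentation and Phenotyping of Plant Point Clouds with a
    Dual Euclidean-Hyperbolic Geometric Graph Encoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semantic stem-leaf segmentation of 3D plant point clouds with a
    geometric graph encoder that fuses an adaptive-kernel graph convolution in
    Euclidean space with a star-transformer encoder over the Poincare ball,
    trained with a combined cross-entropy and triplet objective. Includes the
    surrounding pipeline: labelled point-cloud input/output (ShapeNet-Part
    style text and PLY), radius outlier removal, seeded uniform downsampling,
    reversible unit-ball normalization, farthest-point-sampling graph pooling,
    K-means++ leaf instance clustering with elbow model selection, and
    phenotype extraction (plant height, PCA-aligned leaf length/width, and
    leaf area by ball-pivoting surface reconstruction), together with a
    parametric synthetic-plant generator for controlled evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
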