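Package: nucmorph
Title: Nuclear Histomorphometry for Breast Cancer Risk-Category Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative nuclear histomorphometry from segmented H&E image
    patches. Extracts 216 architecture and shape features per tissue
    compartment (epithelial/stromal) from nuclear centroids, orientations and
    boundaries (Voronoi, Delaunay, minimum spanning tree, nearest-neighbor,
    cell cluster graph and orientation co-occurrence statistics; Hu moments,
    Fourier descriptors and radial shape measures), ranks features (Wilcoxon
    rank-sum, PLS-VIP, MRMR-MID/MIQ), trains patch-level classifiers under
    patient-grouped cross-validation, and aggregates patch calls into
    per-patient Oncotype DX risk-category predictions by threshold-optimized
    patch voting. Includes a seeded synthetic nuclei-cohort generator so the
    full pipeline is testable without clinical images, a classical
    (color-deconvolution + watershed) nucleus segmentation stand-in, and
    GeoJSON/label-mask nuclei I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    deldir,
    igraph,
    jsonlite,
    MASS,
    e1071,
    nnet,
    randomForest,
    EBImage,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
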