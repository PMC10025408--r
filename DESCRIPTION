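Package: phenofield
Title: Multi-Modal Field Phenomics Trait Extraction Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Desk-scale processing pipelines for gantry and drone field
    phenomics data. Converts georeferenced RGB and thermal rasters, PSII
    chlorophyll-fluorescence image stacks, and 3D laser-scan point clouds
    into individual-plant, time-series phenotypic trait tables. Includes
    affine raster georeferencing and UTM projection, plot clipping, a
    pluggable plant-detector contract with a classical reference detector,
    K-means canopy temperature extraction (MEDT/MEAT), F0/FM/FV/FM
    fluorescence traits, point-cloud registration (RANSAC translation,
    landmark affine, ICP) and morphometrics (plant height, bounding and
    convex-hull volumes), agglomerative-clustering plant tracking with
    double-plant flagging, detection evaluation metrics (IoU, recall,
    precision, F1), variance-component repeatability under a mixed model,
    a deterministic synthetic-field generator with ground truth for every
    stage, and a YAML-configured local pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    parallel,
    jsonlite,
    yaml,
    tiff,
    mgcv,
    lme4,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
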