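Package: kdisomap
Title: Kernel Discriminant Isometric Mapping for Facial Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised nonlinear dimensionality reduction by kernel discriminant
    isometric mapping (KDIsomap), together with the spatially enhanced uniform
    local binary pattern (LBP) feature pipeline for grayscale face images, the
    unsupervised kernel Isomap (KIsomap) with Mercer constant-shifting, linear
    and kernel baselines (PCA, LDA, KPCA, KLDA) with out-of-sample extensions,
    a nearest-neighbour classification harness with subject-grouped
    cross-validation, and deterministic synthetic benchmark generators (swiss
    roll, procedural expression image sets).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
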