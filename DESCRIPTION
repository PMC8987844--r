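Package: tilecover
Title: Chopped-Picture Tile Classification for Mapping Flowering Invasive Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and maps amorphous vegetation cover - in particular the
    bright-yellow inflorescences of invasive tall goldenrod (Solidago
    altissima) - in field photographs by the chopped-picture method: images
    are cut into small overlapping square tiles, a shallow convolutional
    neural network classifies each tile as target or background, and the
    per-tile calls are fused back onto the image as a red/green coverage
    mosaic with an estimated cover fraction. Includes size-stratified
    dataset construction with a green-foliage purity rule, seeded data
    augmentation, a built-in CNN training engine, a hard-negative-mining
    retraining loop, tile-level evaluation with Cohen's kappa, a
    cross-camera transferability matrix, and a seeded synthetic-scene
    generator with ground-truth masks so the whole pipeline can be
    exercised and tested without field imagery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
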