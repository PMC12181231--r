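Package: DropletCascade
Title: Cascaded Binary Segmentation and Transformation Kinetics for
    Droplet-Microfluidics Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of time-lapse optical-microscopy frames from
    droplet-microfluidics crystallization screens. Implements a cascade of
    three small binary U-Net segmenters (droplets, then vaterite and calcite
    crystals inside a droplet-masked overlay), K-Means binarization of
    probability maps, connected-object counting, per-droplet content
    classification via contours and minimum enclosing circles, and
    exponential-plateau fitting of the amorphous-calcium-carbonate
    transformation kinetics. Includes a seeded synthetic droplet-scene and
    time-lapse generator with exact ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    minpack.lm,
    png,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
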