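Package: panicleobb
Title: Oriented Bounding-Box Detection and Counting of Rice Panicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A toolkit for oriented (rotated) bounding-box detection of rice
    panicles in UAV field imagery. Provides rotated-rectangle geometry with a
    probabilistic IoU based on the Hellinger distance between Gaussian
    surrogates, exact polygon IoU and rotated non-maximum suppression;
    parsers and converters for rolabelImg XML, DOTA and YOLO-OBB annotation
    formats; image tiling with annotation remapping and OBB-consistent
    augmentation; a seeded generator of synthetic panicle-like oriented
    scenes; a compact oriented detector built from an EfficientNetV2-S style
    backbone with dynamic-convolution feature blocks, trainable on CPU;
    rotated mean-average-precision evaluation; and panicle-count regression
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    generics,
    rlang,
    ggplot2,
    xml2,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
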