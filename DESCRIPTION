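Package: fishdet
Title: Fish Detection and Counting in Overhead Tank Imagery with an
    Attention-Augmented Single-Stage Detector
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and counts fish in top-view images of circular
    recirculating-aquaculture tanks with a single-stage anchor-based
    convolutional detector (CSP backbone, FPN+PAN neck, three prediction
    heads) augmented with coordinate attention, trained with a composite
    CIoU / binary cross-entropy objective and post-processed with linear
    Soft-NMS so that heavily overlapping fish are retained rather than
    suppressed. Includes Mosaic-8 augmentation, IoU-distance K-means prior
    box clustering, Pascal VOC XML and YOLO-text annotation I/O, a
    synthetic top-view tank-scene generator for fully reproducible
    desk-scale experiments, and PR-curve/AP/F1 evaluation. The network,
    reverse-mode gradients and the Adam optimizer are implemented in R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    grDevices,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
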