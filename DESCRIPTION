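Package: spinefuse
Title: Rule-Based Fusion, Anatomical Labeling and Panoptic Evaluation of
    Vertebral Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fuses a semantic (per-pixel) and an instance (per-object)
    segmentation of a lateral spinal X-ray into a single set of separated
    vertebral-body masks using rule-based ensembling: agreement unions,
    instance takeover of merged semantic blobs, and area-based pickup of
    masks missed by one source. Labels each vertebra anatomically by
    anchoring on a reference vertebra (C2 or S1) and zipping along the
    visible column, and evaluates labeled predictions against 8-landmark
    ground-truth annotations with per-class Dice and Panoptic Quality
    (segmentation quality x recognition quality). Includes a seeded
    synthetic spine generator that reproduces the characteristic failure
    modes of each segmentation style, so the whole pipeline is testable
    without images or trained networks, plus a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
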