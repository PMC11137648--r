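Package: spineDSS
Title: MRI-Guided Decision Support for Lumbar Disc Herniation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A fully automatic decision-support pipeline for lumbar disc
    herniation on T2-weighted spine MRI. Detects vertebral bodies on sagittal
    slices and repairs the landmark chain with anatomical distance and angle
    constraints, crops posterior disc regions of interest to diagnose
    herniation, constructs the MSU classification grid from six axial marker
    points to grade herniation size (1-3) and zone (A-C) from the apex of a
    segmented herniation mask, grades disc degeneration (Pfirrmann I-V) with a
    hand-crafted HPI/LBP/PHOG descriptor feeding a 572-300-150-5 multi-layer
    perceptron, and emits rule-based treatment advice. A seeded procedural
    phantom generator provides sagittal and axial slices with exact ground
    truth for end-to-end validation, alongside segmentation and reader-study
    evaluation metrics (DSC, IoU, Fleiss' kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
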