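Package: nbtclassify
Title: Patch-Level Tissue Classification and Lobule Detection for Normal
    Breast Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for compartment-level analysis of haematoxylin-and-eosin
    stained normal breast tissue. Provides Reinhard stain-colour
    normalisation, physical-size-aware whole-slide tessellation, a
    three-class (epithelium / stroma / adipocyte) patch classifier built
    from a frozen convolutional backbone with a trainable dense head,
    CAM and Grad-CAM explainability heatmaps, whole-slide class and
    probability maps, connected-component lobule and peri-lobular region
    detection, QuPath-compatible GeoJSON import/export, and ROC/AUC
    evaluation with DeLong's test. Includes a deterministic synthetic
    H&E-like data generator so the full pipeline is testable end to end
    without any external image download.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
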