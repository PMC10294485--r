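Package: wsimil
Title: Weakly-Supervised Multiple-Instance Learning for Multi-Center
    Whole-Slide Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for tumor-versus-control classification of
    whole-slide histology images under weak (slide-level) supervision across
    multiple data sources. Implements grid tiling with Otsu tissue masking and
    background/contrast filtering, Reinhard color-transfer stain normalization
    in the fast (no brightness standardization) variant, bag-based
    multiple-instance learning with average pooling over tile features and a
    frozen convolutional backbone, patient-level probability aggregation,
    patient-wise stratified and grouped cross-validation with leakage guards,
    cross-dataset evaluation protocols, and a k-nearest-neighbor purity
    diagnostic that quantifies whether learned features separate biological
    classes or datasets of origin. Ships a synthetic multi-center slide
    generator that emulates class-dataset confounding so the whole pipeline is
    testable without access to controlled histology archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
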