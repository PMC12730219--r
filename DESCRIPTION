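Package: mraseg
Title: Small-Object-Aware Aneurysm Segmentation Toolkit for TOF-MRA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A backend-agnostic toolkit for building and evaluating 2D
    instance-segmentation pipelines for intracranial aneurysms on
    Time-of-Flight Magnetic Resonance Angiography (TOF-MRA). Provides NIfTI
    volume ingestion with axial slicing and min-max intensity normalization,
    paired image/mask augmentation (rotation, contrast, gamma, Gaussian
    noise), patient-level k-fold split construction with healthy scans as
    training-only negatives, COCO annotation synthesis (polygon and bitmask
    encodings), physically calibrated small-object proposal filtering with
    dual confidence thresholds, a serializable detector configuration with a
    scripted mock backend, size-stratified pixel-level Dice/precision/recall
    evaluation, and a synthetic vascular phantom generator so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
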