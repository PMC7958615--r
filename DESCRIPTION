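Package: implanteval
Title: Keypoint-Based Evaluation of Dental Implant Detection and
    Peri-Implant Bone Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluates keypoint-based dental-implant detectors on periapical
    radiographs and converts detected landmarks into a radiographic bone-loss
    percentage with a four-level peri-implantitis severity class. Implements
    intersection over union (IoU) and an implant-specific object keypoint
    similarity (OKS) with per-keypoint tolerances calibrated from redundantly
    annotated radiographs, the COCO-style average precision / average recall
    protocol over similarity thresholds 0.50-0.95, mean-OKS observer agreement
    with its analytic normal-model interpretation, keypoint-logit heatmap
    rendering, and a synthetic fixture generator so the whole pipeline is
    testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
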