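Package: pcatriage
Title: Lesion-Level Evaluation and Biopsy-Triage Simulation for Aggressive
    Prostate Cancer Detection on bpMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating voxel-probability outputs of aggressive
    prostate cancer (ISUP >= 2) detectors on biparametric MRI and for
    simulating their use as a biopsy-triage aid. Implements probability-map
    candidate extraction (thresholding, connected components, confidence and
    prostate-gland overlap filters, linear-sum-assignment matching against
    annotated lesions), lesion-level recall/precision and segmentation
    metrics (Dice, Hausdorff distance, average symmetric surface distance,
    relative volume difference), bpMRI preprocessing (grid resampling,
    Z-score and percentile-clipped normalization), a six-category
    biopsy-recommendation scheme with a hybrid radiologist-plus-CAD decision
    protocol, calibrated segmentation-loss arithmetic (label smoothing,
    margin penalty, polynomial learning-rate decay), and a synthetic 3D
    phantom cohort generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
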