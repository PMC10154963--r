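Package: ctlung
Title: Semi-Automated Mouse Micro-CT Lung Segmentation and Radiodensity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scriptable pipeline for quantitative radiodensity analysis of
    murine thoracic micro-CT scans. Extracts the lung by Hounsfield-unit
    thresholding followed by 3D connected-component labeling, component
    selection, morphological mask refinement, and base-to-apex cropping;
    quantifies lung tissue volume within configurable Hounsfield-unit bin
    schemes; supports a semi-manual per-slice region-of-interest workflow with
    offset-slice augmentation; and computes Bland-Altman and regression
    agreement statistics between manual and automated measurements. Ships a
    synthetic mouse-thorax phantom generator with exact ground-truth lung
    masks for end-to-end validation, readers for Analyze 7.5, DICOM series and
    TIFF stacks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    oro.nifti,
    tiff,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
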