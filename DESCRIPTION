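Package: gratiomap
Title: G-Ratio Weighted Imaging with Transmit-Field Bias Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise pipeline for MR g-ratio weighted imaging from
    magnetization transfer saturation (MTsat) and NODDI-derived maps.
    Implements the heuristic transmit-field (B1+) correction of MTsat,
    histology-anchored calibration of the myelin volume fraction, axon
    volume fraction and aggregate g-ratio map computation, SNR-based
    white-matter masking with threshold optimization, ROI aggregation,
    Bland-Altman agreement statistics normalized by dynamic range, and
    tissue-weighted smoothing with coefficient-of-variation analysis.
    Includes a synthetic multi-subject, two-session phantom generator
    with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
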