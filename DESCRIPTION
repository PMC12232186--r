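Package: tilquant
Title: Reproducible Machine Scoring of Tumor-Infiltrating Lymphocytes in H&E Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tile-scale pipeline for machine-derived tumor-infiltrating
    lymphocyte (TIL) quantification on hematoxylin-and-eosin images:
    Macenko-style stain-vector estimation and normalization against a fixed
    reference, watershed nucleus detection with morphometric and chromatic
    feature extraction, a multilayer-perceptron cell classifier over tumor,
    stromal, immune and other cells, and the five electronic TIL variables
    (eTILs, etTILs, esTILs, eaTILs, easTILs). Includes the analytical- and
    clinical-validity statistics used to evaluate such scores (intraclass
    correlation with confidence intervals, tie-corrected Kendall's W,
    coefficient of variation, Kaplan-Meier and log-rank, Cox proportional
    hazards with Schoenfeld diagnostics) and a synthetic-data generator
    producing Beer-Lambert H&E tiles with ground truth, operator score
    matrices with a target intraclass correlation, ordinal Clark grade
    matrices, and survival cohorts with a target hazard ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    nnet,
    survival,
    jsonlite,
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
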