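Package: vmatqa
Title: Simulation and CNN-Based Detection of MLC Modeling Errors in VMAT QA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end feasibility pipeline for detecting multi-leaf
    collimator (MLC) modeling errors in volumetric modulated arc therapy
    (VMAT) quality assurance. Simulates VMAT-like arc plans and planar dose
    maps in a homogeneous cylindrical phantom with the transmission factor
    (TF) and dosimetric leaf gap (DLG) as explicit, perturbable beam-model
    parameters; converts paired error-free/error dose maps into
    mimicked-measurement dose-difference images; assembles labeled image
    datasets with plan-level train/test separation; trains small
    convolutional neural network classifiers for error detection and
    classification; and implements a 2D gamma-index baseline with Wilcoxon
    signed-rank and ROC-based detection from passing rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    pROC,
    png,
    tiff,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
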