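Package: ctprog
Title: Spatial-Temporal CT and Clinical Survival Modelling for Advanced
    Hepatocellular Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prognostic modelling of overall survival in advanced
    hepatocellular carcinoma from longitudinal (baseline and first follow-up)
    CT imaging and clinical covariates. Provides a synthetic CT phantom
    generator with a known survival hazard, representative-slice selection
    from organ and tumor segmentation masks, CT window normalization and
    image preparation, a convolutional-recurrent risk network trained with
    the Cox partial-likelihood loss, a seven-covariate clinical Cox score,
    bivariate-Cox late fusion of the two modalities, a survival evaluation
    suite (Harrell's C, IPCW time-dependent AUC, Kaplan-Meier, log-rank,
    hazard ratios, nomogram, calibration), and Grad-CAM interpretation of
    the imaging model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    Matrix,
    utils,
    grDevices,
    jsonlite,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
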