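Package: lesiontime
Title: Longitudinal Multi-Lesion CT Prognosis with Two-Level Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prognosis modelling from longitudinal multi-lesion CT
    annotations in metastatic cancer. Provides a phantom-cohort simulator with
    known latent risk; Hounsfield-window ROI preprocessing into 3-channel
    patches; a two-level masked attention model that fuses each lesion's time
    series and then the set of lesions into a patient-level risk of poor
    overall survival, trained with a combined cross-entropy and Cox
    partial-likelihood loss; RECIST v1.1 and tumour-burden-change baselines;
    Cox-regression nomogram fusion with calibration diagnostics; and a
    survival evaluation suite (concordance index, one-year AUC, Youden
    cutoff, Kaplan-Meier, log-rank, hazard ratios) with attention-map and
    Grad-CAM explanations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    survival,
    pROC,
    RNifti,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    jsonlite
Config/testthat/edition: 3
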