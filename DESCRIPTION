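Package: pwifet
Title: Sequential Perfusion MRI and Dynamic Amino-Acid PET Classification
    of Glioma Progression Versus Treatment-Related Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies leakage-corrected relative cerebral blood volume
    (rCBV) from dynamic susceptibility contrast (DSC) perfusion MRI signal
    curves, parameterizes dynamic O-(2-[18F]fluoroethyl)-L-tyrosine (FET)
    PET time-activity curves (tumor-to-brain ratios, time-to-peak, late
    slope), derives diagnostic cutoffs by maximizing the product of
    sensitivity and specificity on ROC curves, and combines both modalities
    in a two-stage sequential classifier that first calls tumor progression
    on a high-specificity rCBV threshold and then resolves the remainder
    with combined static and dynamic PET parameters.  Includes confusion
    metrics with exact binomial confidence intervals, DeLong AUC inference,
    leave-one-out cross-validation of the whole fitting procedure, and a
    synthetic cohort generator (parameter-level tables, DSC bolus signals
    with leakage, PET time-activity curves) for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    pROC,
    e1071,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
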