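Package: ebusfusion
Title: Multi-Branch Attention-Based Feature Fusion for Radial EBUS Image
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benign/malignant classification of radial endobronchial
    ultrasound (EBUS) frames with a multi-branch convolutional framework:
    probe-centered multi-scale cropping (4/3/2/1 cm fields), polar
    unwrapping about the probe, three-channel multi-scale composites,
    per-branch CNN encoders fine-tuned then frozen, attention-based
    feature-fusion modules (CBAM and multi-head self-attention), a
    case-count-weighted cross-entropy loss for cohort imbalance, and
    patient-level stratified four-fold cross-validation with the full
    metric panel (accuracy, F1, AUC, PPV, NPV, sensitivity, specificity).
    Ships a synthetic radial-EBUS phantom generator so the entire
    pipeline runs end-to-end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
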