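Package: dmspr
Title: Digital Methylation-Specific PCR Array Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for multiplex digital methylation-specific PCR
    (dMSP) on nanowell-array chips, together with a physics-based simulator so
    every stage can be exercised without laboratory data. Covers chip layout
    and projective mask registration, per-well fluorescence extraction from
    multi-channel 16-bit images, two-population mixture-model well calling
    with a five-sigma positivity threshold, Poisson-corrected absolute copy
    quantification (standard-curve linearity, limits of detection and
    quantification, analytical specificity), the bulk MethyLight mean
    2^-deltaCt comparator statistic, and clinical biomarker-panel evaluation
    (Youden thresholds, leave-one-out cross-validated logistic regression,
    ROC/AUC with stratified bootstrap confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
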