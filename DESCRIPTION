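Package: clbtexture
Title: Contralateral-Breast MRI Texture Features for Tumor Subtype Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Masked-ROI texture radiomics pipeline for classifying invasive
    ductal versus invasive lobular carcinoma from glandular tissue of the
    contralateral breast on T1-weighted pre-contrast MRI. Implements
    first-order, local-neighborhood and gray-level co-occurrence matrix
    (GLCM) texture features over binary glandular masks; ANOVA F-test
    feature ranking with sequential elimination; class-imbalance handling
    by SMOTE oversampling and random under-sampling; stratified splitting
    and ten-fold cross-validation benchmarking of seven classifiers;
    grid-searched random-forest tuning; and confusion-matrix, ROC/AUC and
    paired-run statistical evaluation. A synthetic-phantom generator
    produces per-patient cohorts of correlated Gaussian random fields with
    elliptical glandular masks so the full pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    png,
    tiff,
    class,
    rpart,
    e1071,
    ranger
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
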