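Package: seqdx
Title: Sequencing-Based Breast Cancer Diagnostic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and utilities for sequencing-based breast cancer
    diagnostics: single-gene logistic prediction of ER/PR/HER2 status and a
    penalized linear model for Ki-67 from RNA-seq expression, a composite
    transcriptomic grade built from elastic-net models of the three
    Nottingham grade subcomponents, nearest-shrunken-centroid molecular
    subtyping over a PAM50-style gene panel, gene-level amplification calls
    from low-pass whole-genome copy-number ratios, encodings of the routine
    immunohistochemistry status rules and re-examination concordance logic,
    and matching of somatic alterations to an actionability knowledge base.
    Includes a synthetic cohort generator emulating the statistical structure
    of such studies, ROC/AUC machinery with DeLong variance estimates, nested
    cross-validation, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
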