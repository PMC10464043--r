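Package: ediscreen
Title: Expiratory Disproportion Index Screening for Subglottic Stenosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating the Expiratory Disproportion Index (EDI),
    a spirometry-derived screening statistic for fixed upper-airway
    obstruction such as benign subglottic stenosis. Computes the EDI
    (100 x FEV1 / PEFR) from spirometry indices or sampled flow-volume
    curves, performs a full diagnostic-accuracy evaluation (ROC curve,
    AUC with confidence intervals, optimal cutoff selection, contingency
    tables with exact binomial intervals, group-comparison tests), and
    simulates calibrated synthetic cohorts and mechanistic flow-volume
    curves so the whole pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glue,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
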