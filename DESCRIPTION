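Package: mblater
Title: Clinical Risk Scores for Very Late Recurrence of Atrial
    Fibrillation After Catheter Ablation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and evaluating clinical risk scores for
    very late recurrence of atrial fibrillation (VLRAF, recurrence more
    than 12 months after catheter ablation). Implements the MB-LATER
    score and six comparator scores (APPLE, ALARMc, BASE-AF2, CHADS2,
    CHA2DS2-VASc, HATCH), a seeded synthetic-cohort simulator with a
    proportional-hazards recurrence process and landmark selection flow,
    survival machinery (Kaplan-Meier with Greenwood variance, two-group
    log-rank, univariate Cox screening with Efron tie handling), score
    evaluation (ROC/AUC with DeLong intervals, Youden cutoffs, net
    reclassification and integrated discrimination improvement, decision
    curves), and an end-to-end derivation pipeline producing reproducible
    JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
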