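Package: svrsig
Title: Survival-Time Estimation from Expression Profiles with
    nu-SVR and Inheritable Bi-Objective Genetic Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates patient survival time from miRNA (or other
    transcriptomic) expression profiles with nu-support-vector
    regression whose feature subset and hyperparameters are jointly
    optimized by an inheritable bi-objective combinatorial genetic
    algorithm (IBCGA) with orthogonal-array crossover. Includes
    main-effect-difference (MED) ranking of the selected signature,
    LASSO / elastic-net / multiple-linear-regression baselines under a
    shared 10-fold cross-validation protocol, a censored follow-up
    cohort validation protocol, TCGA-style expression and clinical
    table readers, and a synthetic-cohort generator with a planted
    survival signature for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
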