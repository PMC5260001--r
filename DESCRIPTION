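Package: survmir
Title: Survival-Time Estimation from miRNA Expression with Evolutionary
    nu-SVR Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates patient survival time from miRNA expression cohorts
    by coupling an inheritable bi-objective combinatorial genetic algorithm
    (IBCGA) for simultaneous feature selection and nu-support-vector
    regression hyperparameter tuning, with orthogonal-array intelligent
    crossover. Includes main-effect-difference (MED) feature ranking via
    orthogonal experimental design, per-feature effect and knock-out
    analyses, stepwise multiple-linear-regression and elastic-net
    baselines, a synthetic cohort generator with planted informative
    features, and a small command-line front end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    glmnet,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
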