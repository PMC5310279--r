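Package: survscreen
Title: Variable Selection Strategies for High-Dimensional Censored Survival Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variable selection for right-censored survival outcomes when the
    number of covariates far exceeds the sample size, as in gene-expression
    survival studies. Implements three strategies built around the Cox
    proportional hazards partial likelihood: L1-penalized selection with
    cross-validated tuning (CoxLasso), marginal sure independence screening
    followed by the lasso (CoxSis), and a lasso-conditioned screening strategy
    (CoxSisLasso) that augments the lasso selection with covariates that are
    significant conditional on it, recovering signals that are jointly but not
    marginally associated with survival. Includes unpenalized Cox refitting
    with Wald reports, Harrell's concordance, a generalized R-squared,
    time-dependent ROC/AUC for censored data, hypergeometric gene-set
    over-representation testing, a synthetic-data generator with a known
    sparse Cox model, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
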