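Package: volbandit
Title: Volatility Learning, Exploration, and Delusional Ideation in Bandit Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates and models decision-making under uncertainty in two
    bandit paradigms used in computational psychiatry: a three-option
    probabilistic reversal learning task and the Horizon explore/exploit
    task. Implements a three-level Hierarchical Gaussian Filter (HGF)
    bandit learner with a volatility-coupled softmax response model and
    MAP fitting, a Kalman-filter learning model with a logistic choice
    rule estimated hierarchically by MCMC, descriptive behavioral metrics
    (win-switch rate, lose-stay rate, evidence-integration impairment,
    cognitive-bias questionnaire scores), a synthetic cohort generator
    with planted symptom effects, and a LASSO-then-OLS regression stage
    relating decision-making measures to paranoia and delusional
    ideation. Includes parameter-recovery suites for both models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    purrr,
    Rcpp,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
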