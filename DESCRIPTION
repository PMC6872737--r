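Package: pggsl
Title: Social Learning Models for Repeated Threshold Public Goods Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Behavioral modelling toolkit for the repeated threshold public
    goods game (volunteer's dilemma). Encodes the game rules and payoffs,
    belief learning about others' free-riding driven by social and reward
    prediction errors, individual and group utility computation, and four
    competing trial-wise choice models (social learning, myopic,
    group-utility, inequity-aversion). Provides maximum-likelihood fitting
    with multi-start bounded optimization, BIC and random-effects Bayesian
    model selection, leave-one-block-out cross-validation, parameter
    ablation, synthetic cohort generation with computer-agent co-players for
    parameter and model recovery, a lagged model-free logistic-regression
    analysis, and construction of trial-wise model-based regressors with
    partial-correlation orthogonalization for neuroimaging GLMs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
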