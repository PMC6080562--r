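Package: clustpred
Title: Prediction Models for Clustered Binary Outcomes with Informative
    Random-Effect Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and evaluating risk prediction models for
    clustered binary outcomes using random-intercept logistic regression.
    Implements frequentist prediction that sets the random effect of a new
    cluster to zero, Bayesian posterior prediction that retains the random
    effect and samples it from the posterior random-effects distribution,
    and Bayesian prediction with cluster-level expert opinion encoded as
    equal-probability truncated regions of the random-effects distribution.
    Includes a Polya-Gamma Gibbs sampler for the Bernoulli-logit mixed
    model, a clustered-data simulator with intercept calibration to a
    target prevalence, expert-judgment simulation (optimal and discrepant),
    a performance battery (Brier score, overall and within-cluster C-index
    and calibration slopes), and scenario orchestration for simulation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
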