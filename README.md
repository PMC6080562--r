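# clustpred

Prediction models for clustered binary outcomes that *keep* the cluster
random effect when predicting in previously unseen clusters, using
informative priors built from cluster-level expert opinion.

## The problem

Clinical and veterinary risk models are typically developed on clustered
data — patients within hospitals or practices, animals within herds. The
standard development model is random-intercept logistic regression,

```
logit(p_ij) = β0 + β1 x_ij + u_j,     u_j ~ N(0, σ²_u),
```

but at deployment the new cluster's `u_c` is unknown, and the usual
frequentist practice is to set it to zero, throwing the clustering
structure away. `clustpred` implements the Bayesian alternative: sample
`û_c` per MCMC iteration from the posterior random-effects distribution
`N(0, σ̃²_u⁽ᵏ⁾)` — either in full (weakly informative) or truncated to an
equal-probability region (half, third, or fifth) selected by an expert who
knows the cluster's relative position. Each subject's predicted risk

```
p̂_sc⁽ᵏ⁾ = 1 / (1 + exp(−(β̃0⁽ᵏ⁾ + β̃1⁽ᵏ⁾ x_sc + û_c⁽ᵏ⁾)))
```

is summarized by the median over the K = 200 saved draws. The package also
implements the frequentist analogue (expert opinion as a 2/3/5-level
categorical covariate), a clustered-data simulator with intercept
calibration to a target prevalence, a Pólya-Gamma Gibbs sampler for the
Bernoulli-logit mixed model, and a performance battery (Brier score,
overall and within-cluster C-index and calibration slopes).

## A worked example

```r
library(clustpred)

cfg <- default_config(seed = 42)   # J=50 clusters x 100 subjects, beta1=1.5,
cfg                                # ICC=0.20 (sigma_u2=0.822), prevalence 50%
#> simulation_config: J=50 clusters x n_j=100 subjects (n=5000)
#>   beta0=0.0000  beta1=1.50  sigma_u2=0.8225 (ICC=0.200)
#>   target prevalence=0.50  seed=42

res <- run_scenario(scenario_spec(cfg))   # ~40 s on one core
print(res$table)
#>                                         FREQ    BAYES.WI    BAYES.LI    BAYES.MI     BAYES.HI      FREQ.2       FREQ.3       FREQ.5
#> Overall Brier score                     .192        .192        .172        .168         .164        .171         .168         .165
#> Overall C-index/AUC                     .779        .780        .824        .832         .839        .824         .830         .837
#> Overall calibration slope               .923        .923       1.003       1.004        1.009        .994         .984         .988
#> Within cluster C-index/AUC       .811 [.037] .811 [.037] .811 [.037] .811 [.037]  .811 [.037] .811 [.037]  .811 [.037]  .811 [.037]
#> Within cluster calibration slope .922 [.101] .924 [.103] .974 [.093] .997 [.082] 1.004 [.061] .978 [.091] 1.001 [.082] 1.015 [.067]
```

Reading the table: the Bayesian model with weakly informative priors
(`BAYES.WI`) performs like the frequentist zero-random-effect model
(`FREQ`) — retaining the random effect costs nothing. Adding cluster-level
expert opinion (`BAYES.LI` → `BAYES.HI`, increasingly precise) lowers the
Brier score, raises overall discrimination, and pulls calibration slopes
toward 1; the frequentist categorical-covariate variants (`FREQ.2/3/5`)
show the same pattern. The within-cluster C-index is identical for all
models: cluster-level information cannot reorder subjects *within* a
cluster, only improve discrimination between clusters and calibration.

Robustness of the approach to wrong expert opinion:

```r
run_discrepancy_suite(scenario_spec(cfg))   # 10/30/50% discrepant clusters
```

and the eight one-feature-away sensitivity scenarios:

```r
specs <- sensitivity_specs(scenario_spec(cfg))
names(specs)
#> [1] "icc=0.05" "icc=0.50" "prevalence=0.10" "prevalence=0.25"
#> [5] "J=20" "n_j=20" "beta1=0.5" "beta1=3.0"
```

A thin command-line front end over the same functions is installed at
`inst/cli/clustpred` (subcommands `simulate`, `fit`, `mcmc`, `predict`,
`evaluate`, `run-scenario`, `run-suite`).

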