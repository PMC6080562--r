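---
title: "Predicting in new clusters with informative random-effect priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting in new clusters with informative random-effect priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Risk prediction models are routinely developed on clustered data — patients
within general practices, animals within herds, admissions within hospitals.
A random-intercept logistic model,

$$
\operatorname{logit}(p_{ij}) = \beta_0 + \beta_1 x_{ij} + u_j,
\qquad u_j \sim N(0, \sigma^2_u),
$$

accounts for the within-cluster dependence during development, but the
model is awkward to *apply*: a brand-new cluster has an unknown random
effect. The common frequentist escape is to drop the random-effect term
(set $u_c = 0$ for every new cluster $c$), which discards the clustering
structure precisely where it could help.

`clustpred` implements and evaluates an alternative: keep the random effect
in the prediction model and sample it, per MCMC iteration $k$, from the
posterior random-effects distribution $N\!\left(0, \tilde\sigma^{2(k)}_u\right)$ —
optionally restricted to an *equal-probability truncated region* of that
distribution selected by a cluster-level expert ("this hospital is in the
better half / middle third / lowest fifth"). Each subject then gets a
distribution of $K$ predicted risks

$$
\hat p^{(k)}_{sc} = \operatorname{logit}^{-1}\!\left(
\tilde\beta_0^{(k)} + \tilde\beta_1^{(k)} x_{sc} + \hat u_c^{(k)}\right),
$$

summarized by its median.

## Prediction models

Eight model labels are understood by the scenario runner:

* `FREQ` — maximum-likelihood fit (adaptive Gauss–Hermite quadrature via
  lme4), prediction with $u_c = 0$.
* `BAYES.WI` — Bayesian fit under weakly informative priors
  ($\beta_a \sim N(0, 1000)$, $\sigma^2_u \sim$ Inv-Gamma(0.001, 0.001));
  $\hat u_c^{(k)}$ drawn from the full $N(0, \tilde\sigma_u^{2(k)})$.
* `BAYES.LI` / `BAYES.MI` / `BAYES.HI` — as `BAYES.WI`, but $\hat u_c^{(k)}$
  is drawn from the expert-selected half / third / fifth of the
  distribution. The regions have equal probability $1/m$, so the bounds are
  $\tilde\sigma_u^{(k)}\,\Phi^{-1}\!\big(\tfrac{r-1}{m}\big)$ to
  $\tilde\sigma_u^{(k)}\,\Phi^{-1}\!\big(\tfrac{r}{m}\big)$.
* `FREQ.2` / `FREQ.3` / `FREQ.5` — the frequentist analogue: the expert
  category (2/3/5 empirical-quantile bins of the development clusters'
  random effects) enters the model as a fixed categorical covariate, with
  the lower half / second tertile / third quintile as reference.

A simulated *optimal* expert picks the region actually containing the
cluster's true random effect; a *discrepant* expert picks an adjacent
region (edge regions have one neighbor; interior regions pick either
neighbor by a fair, seeded coin).

## Posterior computation

The sampler uses Pólya-Gamma data augmentation: given
$\omega_{ij} \sim \mathrm{PG}(1, \beta_0 + \beta_1 x_{ij} + u_j)$, the full
conditionals for $(\beta_0, \beta_1)$ and each $u_j$ are Gaussian and the
conditional for $\sigma^2_u$ is Inv-Gamma$(a + J/2,\; b + \sum_j u_j^2/2)$,
so the Gibbs sampler has no tuning parameters and is reproducible from a
seed. The PG(1, z) variates are generated by the exact alternating-series
rejection method (Devroye; Polson–Scott–Windle), written against R's RNG.

Numerical and design choices fixed as package defaults:

* **Chains and draws.** 2 chains, thinning interval 10, 100 saved draws per
  chain (200 total), so every subject gets a 200-draw risk distribution.
* **Burn-in 5000 iterations**, deliberately conservative. Convergence is
  checked by the Gelman–Rubin potential scale reduction factor; all
  parameters must be below 1.1 or the result is flagged with a warning.
* **Initial values.** $(\beta_0, \beta_1)$ at the plain logistic-regression
  estimates, $u_j = 0$, $\sigma^2_u = 1$ — deterministic and close to the
  posterior mode, so the conservative burn-in is comfortably sufficient.
* **Prior mean zero** for the coefficients; the variance 1000 and
  Inv-Gamma(0.001, 0.001) hyperparameters express near-ignorance.

## Truncated sampling

$\hat u_c^{(k)}$ for region $r$ on scale $m$ is sampled by inverse CDF on
the probability scale: $U \sim \mathrm{Unif}\big(\tfrac{r-1}{m},
\tfrac{r}{m}\big)$, $\hat u_c^{(k)} = \tilde\sigma_u^{(k)} \Phi^{-1}(U)$.
This is exact (no rejection inefficiency in the 1/5-scale tails), and the
probability-scale region is invariant to $\sigma_u$, so the expert's
positional statement is honored for every posterior draw of the variance.
It also makes the untruncated case the $m = 1$ special case, draw for draw,
which the tests exploit. One $\hat u_c^{(k)}$ is drawn per cluster per
iteration and shared by all the cluster's subjects.

The expert's *judgment* is made against the true generating
$\sigma_u$ (the simulated expert knows the cluster's position in the real
world), while the prediction-time bounds use each iteration's sampled
$\tilde\sigma_u^{(k)}$ — position is elicited once, re-expressed per draw.

## The data generator

The generator draws $x \sim N(0,1)$ per
subject, $u_j \sim N(0, \sigma^2_u)$ per cluster,
$y \sim \text{Bernoulli}(\operatorname{logit}^{-1}(\beta_0 + \beta_1 x + u))$.
Defaults: $J = 50$ clusters of $n_j = 100$ (5000 subjects), $\beta_1 = 1.5$,
ICC $= 0.20$ — i.e. $\sigma^2_u = \mathrm{ICC} \cdot (\pi^2/3)/(1 -
\mathrm{ICC}) = 0.822$ on the latent-threshold scale — and 50% marginal
prevalence.

* **Intercept calibration.** Rather than adjusting $\beta_0$ by trial and
  error to reach the target prevalence, $x$ and $u$ are collapsed into one
  normal $Z \sim N(0, \beta_1^2 + \sigma^2_u)$ and
  $E[\operatorname{logit}^{-1}(\beta_0 + Z)]$ is evaluated by 64-node
  Gauss–Hermite quadrature and inverted by bracketed root finding to
  tolerance $10^{-6}$ — deterministic, and verified against a Monte Carlo
  oracle in the tests.
* **Substreams.** The master seed is split into named substreams (predictor,
  random effects, outcomes; development vs prediction role), so the
  development and new-cluster datasets are independent draws from the same
  population and regenerating one stage never perturbs another.
* **Quantile ties.** Expert-category encoding places a value equal to an
  empirical bin boundary into the lower bin — deterministic and documented.
* Equal cluster sizes only are generated; unequal sizes
  are accepted on read.

What the generator does *not* emulate about real data: covariate
measurement error, non-normal or skewed cluster effects, cluster-size
informativeness, multiple correlated predictors, and drift between
development and deployment populations. Passing tests therefore demonstrate
correctness of the machinery and the qualitative conclusions under this
generating model, not transportability to any empirical setting.

## Evaluation battery

* **Brier score** — mean squared difference between outcome and predicted
  risk.
* **C-index** — Mann–Whitney concordance (= area under the ROC curve), ties
  credited 0.5, computed from average ranks.
* **Calibration slope** — in simulation mode, the OLS slope of the *true
  latent risk* on the predicted risk (truth is available); in empirical
  mode, the logistic slope of the observed outcome on the estimated linear
  predictor. The mode is always chosen explicitly by the caller.
* **Within-cluster versions** of the C-index and calibration slope are
  computed per cluster and summarized as mean and SD ($n-1$ denominator)
  over clusters; clusters where a metric is undefined (single outcome
  class, constant predictions — relevant for the $n_c = 20$ sensitivity
  scenario) are excluded from the summary and counted.

A structural fact the tests verify: when every posterior draw of
$\beta_1$ is positive, the median predicted risk is monotone in $x$ within
a cluster, so *within-cluster* rankings — and hence within-cluster
C-indexes — are identical across all eight models. Cluster-level
information can only improve discrimination *between* clusters and
calibration.

## Scenario orchestration

`run_scenario()` generates one development and one prediction dataset from
the same configuration, fits every requested model on the identical pair
(one posterior sample serves all Bayesian variants), and emits a results
comparison table across models. `run_discrepancy_suite()` re-predicts the
truncated-prior models with 10/30/50% of new clusters judged discrepantly;
the discrepant-cluster set is drawn once per percentage and shared across
the three scales, which makes the scale comparison exact. `sensitivity_specs()` builds the eight one-feature-away
scenarios (ICC 0.05/0.50, prevalence 10%/25%, $J = 20$, $n_j = 20$,
$\beta_1$ 0.5/3.0).

Replication across seeds is built in: seed-to-seed variability of a single
scenario run is substantial (between-seed
SD of the overall C-index is roughly 0.008–0.013 at the default scale), so
the package's study-level tests and the acceptance script compare
*replication means* — 10 replicate scenario runs of 5000 development and
5000 prediction subjects each, plus 100 lighter replicates (shortened
burn-in, thinning 2) for the parameter-recovery coverage check. These
problem sizes are the package's chosen desk-scale defaults; all of them are
plain arguments and can be raised.

## Known limitations

* One subject-level predictor and a random intercept only; no random
  slopes, no multiple predictors, no non-normal random effects.
* Equal-probability regions only. Equal-*width* division of the
  random-effects distribution — which would change how discrepant opinion
  behaves in the tails — is deliberately out of scope, as it is in the
  study's own discussion.
* Discrepant opinion is always an *adjacent* region; fully random
  misjudgment is not modelled.
* The Bayesian machinery assumes the Bernoulli-logit link throughout
  (Pólya-Gamma augmentation is logit-specific).

## A worked run

```{r}
library(clustpred)
spec <- scenario_spec(default_config(seed = 42))
res <- run_scenario(spec)   # ~40 s: 1 ML fit, 3 FREQ.k fits, 1 MCMC, 8 evals
print(res)
```
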