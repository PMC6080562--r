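#' Model labels understood by the scenario runner
#'
#' `FREQ` is maximum-likelihood estimation with new-cluster random effects
#' set to zero; `BAYES.WI` retains the random effect and samples it from the
#' full posterior random-effects distribution; `BAYES.LI`/`BAYES.MI`/
#' `BAYES.HI` sample it from the expert-selected half/third/fifth of that
#' distribution; `FREQ.2`/`FREQ.3`/`FREQ.5` add the expert opinion to the
#' frequentist model as a categorical covariate with 2/3/5 levels.
#'
#' @export
model_labels <- c("FREQ", "BAYES.WI", "BAYES.LI", "BAYES.MI", "BAYES.HI",
                  "FREQ.2", "FREQ.3", "FREQ.5")

trunc_scale <- c(BAYES.LI = 2L, BAYES.MI = 3L, BAYES.HI = 5L)
freqk_scale <- c(FREQ.2 = 2L, FREQ.3 = 3L, FREQ.5 = 5L)

#' Specify a simulation scenario
#'
#' Bundles the generating configuration, the set of prediction models to
#' compare, the proportion of new clusters receiving discrepant expert
#' opinion, and the MCMC settings (2 chains thinned by 10 with 100 saved
#' draws each, i.e. 200 posterior samples, by default).
#'
#' @param config A [simulation_config()].
#' @param models Subset of [model_labels].
#' @param discrepancy_pct Proportion of new clusters whose expert judgment
#'   is discrepant (applies to the truncated-prior models only).
#' @param mcmc List with `chains`, `thin`, `n_save`, `burn_in`.
#' @param seed Master seed for the scenario's analysis stages (judgments,
#'   MCMC, prediction draws); defaults to the configuration seed.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(config = default_config(),
                          models = model_labels,
                          discrepancy_pct = 0,
                          mcmc = list(chains = 2L, thin = 10L, n_save = 100L,
                                      burn_in = 5000L),
                          seed = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            all(models %in% model_labels),
            discrepancy_pct >= 0, discrepancy_pct <= 1)
  defaults <- list(chains = 2L, thin = 10L, n_save = 100L, burn_in = 5000L)
  defaults[names(mcmc)] <- mcmc
  structure(list(config = config, models = models,
                 discrepancy_pct = discrepancy_pct, mcmc = defaults,
                 seed = as.integer(seed %||% config$seed)),
            class = "scenario_spec")
}

# Fit every ingredient a scenario needs exactly once: the development and
# prediction datasets (same configuration, independent substreams), the ML
# fits, and the posterior draws shared by all Bayesian prediction variants.
scenario_fit <- function(spec) {
  config <- spec$config
  dev <- generate_dataset(config, "development")
  newd <- generate_dataset(config, "prediction")

  dev_cl <- sort(unique(dev$cluster_id))
  new_cl <- sort(unique(newd$cluster_id))
  dev_u <- dev$true_u[match(dev_cl, dev$cluster_id)]
  new_u <- newd$true_u[match(new_cl, newd$cluster_id)]

  st <- list(spec = spec, config = config, dev = dev, newd = newd,
             dev_u = dev_u, new_u = new_u, new_cl = new_cl)

  if (any(spec$models %in% c("FREQ", names(freqk_scale))))
    st$freq_fit <- fit_glmm_ml(dev)
  for (lab in intersect(spec$models, names(freqk_scale))) {
    m <- freqk_scale[[lab]]
    st$freqk_fits[[lab]] <- fit_glmm_ml(
      dev, expert_covariate = encode_expert_categories(dev_u, dev_u, m))
  }
  if (any(startsWith(spec$models, "BAYES")))
    st$draws <- run_mcmc(dev, chains = spec$mcmc$chains,
                         thin = spec$mcmc$thin, n_save = spec$mcmc$n_save,
                         burn_in = spec$mcmc$burn_in,
                         seed = substream_seed(spec$seed, "mcmc"))
  st
}

# Discrepant-cluster assignment for a given percentage: deterministic in the
# scenario seed and shared across the three truncation scales.
scenario_disc_set <- function(st, pct) {
  if (pct == 0) return(st$new_cl[0])
  set.seed(substream_seed(st$spec$seed, sprintf("discrepant-pct-%g", pct)))
  assign_discrepant_clusters(st$new_cl, pct)
}

# Point predictions (and full prediction objects) for one model label.
scenario_predict <- function(st, label, pct = 0) {
  spec <- st$spec
  if (label == "FREQ")
    return(list(p_hat = predict_freq(st$freq_fit, st$newd)))
  if (label %in% names(freqk_scale)) {
    m <- freqk_scale[[label]]
    cats <- encode_expert_categories(st$new_u, st$dev_u, m)
    return(list(p_hat = predict_freq(st$freqk_fits[[label]], st$newd,
                                     expert_categories = cats)))
  }
  pred_seed <- substream_seed(spec$seed, paste0("predict-", label))
  if (label == "BAYES.WI") {
    res <- predict_bayes_weakly(st$draws, st$newd, seed = pred_seed)
  } else {
    m <- trunc_scale[[label]]
    disc <- scenario_disc_set(st, pct)
    set.seed(substream_seed(spec$seed, sprintf("judgment-m%d-pct-%g", m, pct)))
    judgments <- elicit_judgments(st$new_cl, st$new_u,
                                  sqrt(st$config$sigma_u2), m,
                                  discrepant_clusters = disc)
    res <- predict_bayes_truncated(st$draws, st$newd, judgments,
                                   seed = pred_seed, model = label)
  }
  list(p_hat = res$risk_point, result = res)
}

#' Run one simulation scenario end to end
#'
#' Generates one development and one prediction dataset from the scenario's
#' configuration (independent random-number substreams), fits every
#' requested model on the development data, predicts the new-cluster
#' outcomes, and evaluates each model with the full performance battery.
#' All models consume the identical pair of datasets, and all Bayesian
#' variants share one set of posterior draws.
#'
#' @param spec A [scenario_spec()].
#' @return A `scenario_result` with `table` (a `results_table`), `metrics`
#'   (named `metrics_report` list), `predictions` (named list of per-subject
#'   predicted-risk vectors), and the `spec`.
#' @export
run_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  st <- scenario_fit(spec)
  preds <- lapply(setNames(spec$models, spec$models), function(lab)
    scenario_predict(st, lab, pct = spec$discrepancy_pct)$p_hat)
  metrics <- lapply(preds, function(p)
    metrics_report(st$newd$y, p, st$newd$true_p, st$newd$cluster_id))
  structure(list(table = results_table(metrics), metrics = metrics,
                 predictions = preds, spec = spec),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cfg <- x$spec$config
  cat(sprintf(
    "scenario_result: n=%d (J=%d, n_j=%d), beta1=%g, ICC=%.2f, prevalence=%g\n",
    cfg$J * cfg$n_j, cfg$J, cfg$n_j, cfg$beta1, cfg$icc,
    cfg$target_prevalence))
  print(x$table)
  invisible(x)
}

#' Discrepant-expert-opinion study
#'
#' Fits the scenario once, then evaluates the truncated-prior models
#' (`BAYES.LI`, `BAYES.MI`, `BAYES.HI`) with each requested proportion of
#' new clusters receiving discrepant (adjacent-region) expert opinion.  The
#' discrepant-cluster set is drawn once per percentage and reused across the
#' three scales; `FREQ` and `BAYES.WI` reference columns are included.
#'
#' @param spec A [scenario_spec()]; must request the truncated-prior models.
#' @param pcts Proportions of clusters with discrepant opinion.
#' @return A `scenario_result` whose table has columns `FREQ`, `BAYES.WI`,
#'   and one column per truncated-prior model and percentage (e.g.
#'   `BAYES.LI 10%`).
#' @export
run_discrepancy_suite <- function(spec, pcts = c(0.10, 0.30, 0.50)) {
  stopifnot(inherits(spec, "scenario_spec"),
            all(names(trunc_scale) %in% spec$models))
  st <- scenario_fit(spec)
  preds <- list()
  for (lab in intersect(c("FREQ", "BAYES.WI"), spec$models))
    preds[[lab]] <- scenario_predict(st, lab)$p_hat
  for (lab in names(trunc_scale))
    for (pct in pcts) {
      col <- if (pct == 0) lab else sprintf("%s %d%%", lab, round(100 * pct))
      preds[[col]] <- scenario_predict(st, lab, pct = pct)$p_hat
    }
  metrics <- lapply(preds, function(p)
    metrics_report(st$newd$y, p, st$newd$true_p, st$newd$cluster_id))
  structure(list(table = results_table(metrics), metrics = metrics,
                 predictions = preds, spec = spec, pcts = pcts),
            class = "scenario_result")
}

#' Sensitivity-analysis scenario grid
#'
#' Eight scenarios, each differing from the default configuration in exactly
#' one generating feature: ICC 0.05 or 0.50, prevalence 10% or 25%, 20
#' clusters of 100 (n = 2000), 50 clusters of 20 (n = 1000), and predictor
#' coefficient 0.5 or 3.0.
#'
#' @param base A `scenario_spec` providing defaults.
#' @return A named list of eight `scenario_spec`s.
#' @export
sensitivity_specs <- function(base = scenario_spec()) {
  cfg <- base$config
  remake <- function(...) {
    args <- list(J = cfg$J, n_j = cfg$n_j, beta1 = cfg$beta1, icc = cfg$icc,
                 target_prevalence = cfg$target_prevalence, seed = cfg$seed)
    override <- list(...)
    args[names(override)] <- override
    spec <- base
    spec$config <- do.call(simulation_config, args)
    spec
  }
  list(
    `icc=0.05` = remake(icc = 0.05),
    `icc=0.50` = remake(icc = 0.50),
    `prevalence=0.10` = remake(target_prevalence = 0.10),
    `prevalence=0.25` = remake(target_prevalence = 0.25),
    `J=20` = remake(J = 20L),
    `n_j=20` = remake(n_j = 20L),
    `beta1=0.5` = remake(beta1 = 0.5),
    `beta1=3.0` = remake(beta1 = 3.0))
}

#' Run the eight sensitivity analyses
#'
#' @param base A `scenario_spec` providing the default settings.
#' @return A named list of eight `scenario_result`s.
#' @export
run_sensitivity_suite <- function(base = scenario_spec()) {
  lapply(sensitivity_specs(base), run_scenario)
}

#' Assemble a results table from per-model metric reports
#'
#' @param metrics Named list of `metrics_report` objects (one per model).
#' @return A numeric `results_table` data frame: metrics as rows, models as
#'   columns.
#' @export
results_table <- function(metrics) {
  fields <- c("Overall Brier score" = "brier",
              "Overall C-index/AUC" = "c_index_overall",
              "Overall calibration slope" = "cal_slope_overall",
              "Within cluster C-index/AUC (mean)" = "c_index_within_mean",
              "Within cluster C-index/AUC (sd)" = "c_index_within_sd",
              "Within cluster calibration slope (mean)" = "cal_slope_within_mean",
              "Within cluster calibration slope (sd)" = "cal_slope_within_sd")
  tab <- as.data.frame(lapply(metrics, function(m)
    vapply(fields, function(f) m[[f]], 0)), check.names = FALSE,
    row.names = names(fields))
  class(tab) <- c("results_table", "data.frame")
  tab
}

#' @export
print.results_table <- function(x, digits = 3, ...) {
  fmt <- function(v) sub("^(-?)0\\.", "\\1.", sprintf("%.3f", v))
  pair <- function(mean_row, sd_row)
    paste0(fmt(unlist(x[mean_row, ])), " [", fmt(unlist(x[sd_row, ])), "]")
  out <- rbind(
    "Overall Brier score" = fmt(unlist(x["Overall Brier score", ])),
    "Overall C-index/AUC" = fmt(unlist(x["Overall C-index/AUC", ])),
    "Overall calibration slope" = fmt(unlist(x["Overall calibration slope", ])),
    "Within cluster C-index/AUC" = pair("Within cluster C-index/AUC (mean)",
                                        "Within cluster C-index/AUC (sd)"),
    "Within cluster calibration slope" = pair(
      "Within cluster calibration slope (mean)",
      "Within cluster calibration slope (sd)"))
  colnames(out) <- names(x)
  print(out, quote = FALSE, right = TRUE)
  invisible(x)
}
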