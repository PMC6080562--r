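# Replication experiment shared by the scenario-level tests: the default
# scenario (J = 50, n_j = 100, beta1 = 1.5, ICC = 0.20, prevalence 50%) run
# under several fresh seeds, with every prediction model evaluated on the
# same dataset pair per replicate, plus the truncated-prior models under
# discrepant expert opinion at 10/30/50% of new clusters.  One posterior
# sample per replicate serves all Bayesian variants.  Computed lazily and
# cached for the duration of the test run.

replication_cache <- new.env(parent = emptyenv())

discrepancy_labels <- as.vector(outer(
  c("BAYES.LI", "BAYES.MI", "BAYES.HI"), c(10, 30, 50),
  function(l, p) sprintf("%s %d%%", l, p)))

default_replicates <- function(R = 10L) {
  key <- paste0("reps", R)
  if (!is.null(replication_cache[[key]])) return(replication_cache[[key]])
  tabs <- lapply(seq_len(R), function(i) {
    spec <- scenario_spec(default_config(seed = 20000L + i))
    st <- clustpred:::scenario_fit(spec)
    preds <- lapply(stats::setNames(model_labels, model_labels), function(l)
      clustpred:::scenario_predict(st, l)$p_hat)
    for (lab in c("BAYES.LI", "BAYES.MI", "BAYES.HI"))
      for (pct in c(0.10, 0.30, 0.50))
        preds[[sprintf("%s %d%%", lab, round(100 * pct))]] <-
          clustpred:::scenario_predict(st, lab, pct)$p_hat
    metrics <- lapply(preds, function(p)
      metrics_report(st$newd$y, p, st$newd$true_p, st$newd$cluster_id))
    results_table(metrics)
  })
  replication_cache[[key]] <- tabs
  tabs
}

# element-wise mean of replicate results tables
replication_means <- function(tabs) {
  Reduce(`+`, lapply(tabs, function(t) as.matrix(as.data.frame(t)))) /
    length(tabs)
}
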