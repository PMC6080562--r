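#' Predicted risk from a linear predictor
#'
#' `plogis(beta0 + beta1 * x + u)`, the inverse-logit of the linear
#' predictor including the cluster random effect.  Vectorized and
#' overflow-safe.
#'
#' @param beta0,beta1 Regression coefficients.
#' @param u Cluster random effect.
#' @param x Predictor value.
#' @return Predicted risk in (0, 1).
#' @examples
#' predicted_risk(-1.35, 1.07, 0.50, 1.1) # 0.58
#' @export
predicted_risk <- function(beta0, beta1, u, x) {
  stopifnot(all(is.finite(beta0)), all(is.finite(beta1)), all(is.finite(u)),
            all(is.finite(x)))
  plogis(beta0 + beta1 * x + u)
}

#' Median point prediction from a vector of risk draws
#'
#' @param risk_draws Numeric vector of predicted-risk draws.
#' @return The empirical median (midpoint convention for even lengths).
#' @export
summarize_point <- function(risk_draws) {
  if (length(risk_draws) == 0) stop("`risk_draws` is empty")
  median(risk_draws)
}

new_prediction_result <- function(model, new_data, risk_draws, u_draws,
                                  clusters) {
  structure(list(model = model,
                 cluster_id = new_data$cluster_id,
                 x = new_data$x,
                 risk_point = unname(apply(risk_draws, 1L, median)),
                 risk_draws = risk_draws,
                 u_draws = u_draws,
                 clusters = clusters),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result [%s]: %d subjects, %d clusters, K=%d draws\n",
              x$model, length(x$risk_point), nrow(x$u_draws),
              ncol(x$risk_draws)))
  cat(sprintf("  median predicted risk %.3f (range %.3f-%.3f)\n",
              median(x$risk_point), min(x$risk_point), max(x$risk_point)))
  invisible(x)
}

# Shared machinery for Bayesian prediction: per posterior iteration k, each
# new cluster's random effect is u_c^(k) = sigma_u^(k) * qnorm(U_ck) with
# U_ck uniform on the probability-scale region of that cluster's judgment
# (the whole of (0,1) when no truncation applies).  Inverse-CDF sampling is
# exact in the tails and makes the untruncated case a special case of the
# truncated one, draw for draw.
predict_bayes_engine <- function(draws, new_data, seed, region, m, model) {
  stopifnot(inherits(draws, "posterior_draws"),
            inherits(new_data, "clustered_dataset"))
  K <- nrow(draws)
  if (K < 2L) stop("need at least 2 posterior draws")
  clusters <- sort(unique(new_data$cluster_id))
  C <- length(clusters)
  cl <- match(new_data$cluster_id, clusters)

  set.seed(substream_seed(seed, "new-cluster-u"))
  U <- matrix(runif(C * K), C, K)
  U <- (region - 1) / m + U / m   # region is a length-C vector, recycled by column
  sigma_k <- sqrt(draws$sigma_u2)
  u_draws <- qnorm(U) * matrix(sigma_k, C, K, byrow = TRUE)
  rownames(u_draws) <- clusters

  lp <- matrix(draws$beta0, length(cl), K, byrow = TRUE) +
    outer(new_data$x, draws$beta1) + u_draws[cl, , drop = FALSE]
  new_prediction_result(model, new_data, plogis(lp), u_draws, clusters)
}

#' Bayesian prediction with weakly informative new-cluster random effects
#'
#' For each posterior iteration k, a fresh random effect for every new
#' cluster is drawn from the full N(0, sigma_u2^(k)) distribution; the
#' predicted risk for each subject is then the inverse-logit of
#' `beta0^(k) + beta1^(k) x + u_c^(k)`.  The point prediction per subject
#' is the median over all K draws.
#'
#' @param draws A `posterior_draws` object from [run_mcmc()].
#' @param new_data A `clustered_dataset` of new-cluster subjects.
#' @param seed Seed for the new-cluster random-effect draws.
#' @return A `prediction_result` with per-subject `risk_draws` (n x K),
#'   `risk_point`, and per-cluster `u_draws` (C x K).
#' @export
predict_bayes_weakly <- function(draws, new_data, seed = 1L) {
  predict_bayes_engine(draws, new_data, seed, region = rep(1L,
    length(unique(new_data$cluster_id))), m = 1L, model = "BAYES.WI")
}

#' Bayesian prediction with truncated informative priors from expert opinion
#'
#' As [predict_bayes_weakly()], but each new cluster's random effect is
#' drawn, in every posterior iteration, from N(0, sigma_u2^(k)) truncated to
#' the expert-selected equal-probability region: u = sigma^(k) * qnorm(U)
#' with U uniform on ((r-1)/m, r/m).  The probability-scale region is
#' invariant to sigma, so the expert's positional statement is honored for
#' every posterior draw of the variance.
#'
#' @param draws A `posterior_draws` object.
#' @param new_data A `clustered_dataset` of new-cluster subjects.
#' @param judgments An `expert_judgments` data frame covering every new
#'   cluster, all on one scale `m`.
#' @param seed Seed for the truncated random-effect draws.
#' @param model Label for the result (derived from `m` when `NULL`).
#' @return A `prediction_result`.
#' @export
predict_bayes_truncated <- function(draws, new_data, judgments, seed = 1L,
                                    model = NULL) {
  stopifnot(inherits(judgments, "data.frame"),
            all(c("cluster_id", "m", "region") %in% names(judgments)))
  m <- unique(judgments$m)
  if (length(m) != 1L) stop("all judgments must share one scale `m`")
  if (any(judgments$region < 1 | judgments$region > m))
    stop("region index incompatible with scale m")
  clusters <- sort(unique(new_data$cluster_id))
  idx <- match(clusters, judgments$cluster_id)
  if (anyNA(idx))
    stop("missing expert judgment for cluster(s): ",
         paste(clusters[is.na(idx)], collapse = ", "))
  model <- model %||%
    switch(as.character(m), `1` = "BAYES.WI", `2` = "BAYES.LI",
           `3` = "BAYES.MI", `5` = "BAYES.HI", paste0("BAYES.TR", m))
  predict_bayes_engine(draws, new_data, seed,
                       region = judgments$region[idx], m = m, model = model)
}

#' Export per-subject predictions as a flat table
#'
#' @param result A `prediction_result`.
#' @param draws Include the K individual risk draws as wide columns?
#' @return A data frame with `model`, `cluster_id`, `x`, `risk_point` and
#'   optionally `draw_1..draw_K`.
#' @export
prediction_table <- function(result, draws = FALSE) {
  stopifnot(inherits(result, "prediction_result"))
  out <- data.frame(model = result$model, cluster_id = result$cluster_id,
                    x = result$x, risk_point = result$risk_point)
  if (draws) {
    wide <- as.data.frame(result$risk_draws)
    names(wide) <- paste0("draw_", seq_len(ncol(wide)))
    out <- cbind(out, wide)
  }
  out
}
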