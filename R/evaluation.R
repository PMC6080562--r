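#' Brier score
#'
#' Mean squared difference between observed binary outcomes and predicted
#' risks; 0 is perfect, 0.25 is the score of the uninformative constant 0.5.
#'
#' @param y 0/1 outcome vector.
#' @param p_hat Predicted risks in \[0, 1\].
#' @return The Brier score.
#' @export
brier_score <- function(y, p_hat) {
  if (length(y) != length(p_hat)) stop("`y` and `p_hat` differ in length")
  stopifnot(all(y %in% 0:1), all(p_hat >= 0 & p_hat <= 1))
  mean((y - p_hat)^2)
}

#' Concordance index (area under the ROC curve)
#'
#' Mann-Whitney concordance: the probability that a randomly chosen case
#' scores higher than a randomly chosen control, with ties credited 0.5.
#' Computed from average ranks, which is exactly the tie-corrected
#' Mann-Whitney statistic.
#'
#' @param y 0/1 outcome vector.
#' @param score Predicted risks or any monotone score.
#' @return The C-index in \[0, 1\].
#' @export
c_index <- function(y, score) {
  if (length(y) != length(score)) stop("`y` and `score` differ in length")
  stopifnot(all(y %in% 0:1))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("C-index is undefined when only one outcome class is present")
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration slope against the true latent risks
#'
#' Ordinary least-squares slope of the true risk on the predicted risk (the
#' simulation-mode calibration measure, where latent risks are known);
#' 1 indicates perfect calibration.
#'
#' @param p_hat Predicted risks.
#' @param p_true True latent risks.
#' @return The regression slope `cov(p_hat, p_true) / var(p_hat)`.
#' @export
calibration_slope_true <- function(p_hat, p_true) {
  if (length(p_hat) != length(p_true)) stop("length mismatch")
  if (length(p_hat) < 2L) stop("need at least 2 observations")
  v <- var(p_hat)
  if (v == 0) stop("calibration slope undefined: `p_hat` is constant")
  stats::cov(p_hat, p_true) / v
}

#' Calibration slope against observed outcomes
#'
#' Logistic-regression slope of the observed 0/1 outcome on the estimated
#' linear predictor (the empirical-data calibration measure, used when true
#' risks are unavailable); 1 indicates perfect calibration.
#'
#' @param y 0/1 outcome vector.
#' @param lp_hat Estimated linear predictors (logit of predicted risk).
#' @return The logistic slope, with attribute `separation` set to `TRUE`
#'   when the fit shows signs of separation.
#' @export
calibration_slope_observed <- function(y, lp_hat) {
  stopifnot(all(y %in% 0:1))
  if (length(unique(y)) < 2L)
    stop("calibration slope undefined: single outcome class")
  if (var(lp_hat) == 0)
    stop("calibration slope undefined: `lp_hat` is constant")
  warned <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ lp_hat, family = binomial("logit")),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  slope <- unname(coef(fit)[2])
  sep <- warned || abs(slope) > 15
  if (sep) warning("possible separation in the calibration fit")
  structure(slope, separation = sep)
}

#' Within-cluster discrimination and calibration
#'
#' Computes the C-index (against observed outcomes) and the calibration
#' slope (against true risks) separately in each cluster, then summarizes
#' them as a mean and a standard deviation (n-1 denominator) over clusters.
#' Clusters in which a metric is undefined (single outcome class, constant
#' predictions) are excluded from that metric's summary and counted.
#'
#' @param y 0/1 outcomes.
#' @param p_hat Predicted risks.
#' @param p_true True latent risks, or `NULL` to skip calibration slopes.
#' @param cluster_id Cluster identifiers, one per subject.
#' @return A list with `per_cluster` (data frame of cluster, c_index,
#'   cal_slope), `c_index_mean/sd`, `cal_slope_mean/sd`, and
#'   `n_clusters_excluded` (clusters with at least one undefined metric).
#' @export
within_cluster_metrics <- function(y, p_hat, p_true, cluster_id) {
  stopifnot(length(y) == length(p_hat), length(y) == length(cluster_id))
  clusters <- sort(unique(cluster_id))
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  per <- do.call(rbind, lapply(clusters, function(cl) {
    i <- cluster_id == cl
    data.frame(
      cluster_id = cl,
      c_index = safe(c_index(y[i], p_hat[i])),
      cal_slope = if (is.null(p_true)) NA_real_
                  else safe(calibration_slope_true(p_hat[i], p_true[i])))
  }))
  summarize <- function(v) c(mean = mean(v[!is.na(v)]),
                             sd = sd(v[!is.na(v)]))
  ci <- summarize(per$c_index)
  cs <- if (is.null(p_true)) c(mean = NA_real_, sd = NA_real_)
        else summarize(per$cal_slope)
  excluded <- is.na(per$c_index) |
    (if (is.null(p_true)) FALSE else is.na(per$cal_slope))
  list(per_cluster = per,
       c_index_mean = unname(ci["mean"]), c_index_sd = unname(ci["sd"]),
       cal_slope_mean = unname(cs["mean"]), cal_slope_sd = unname(cs["sd"]),
       n_clusters_excluded = sum(excluded))
}

#' Full performance battery for one prediction model
#'
#' Overall Brier score and C-index against observed outcomes, overall
#' calibration slope against true latent risks, and within-cluster C-index
#' and calibration slope summarized over clusters.
#'
#' @param y 0/1 outcomes for the new-cluster subjects.
#' @param p_hat Predicted risks (point predictions).
#' @param p_true True latent risks (`NULL` for empirical data, in which case
#'   calibration slopes are reported against observed outcomes via
#'   [calibration_slope_observed()]).
#' @param cluster_id Cluster identifiers.
#' @return A `metrics_report` list with fields `brier`, `c_index_overall`,
#'   `cal_slope_overall`, `c_index_within_mean`, `c_index_within_sd`,
#'   `cal_slope_within_mean`, `cal_slope_within_sd`, `n_clusters_excluded`.
#' @export
metrics_report <- function(y, p_hat, p_true, cluster_id) {
  overall_slope <- if (is.null(p_true)) {
    as.numeric(calibration_slope_observed(y, qlogis(p_hat)))
  } else {
    calibration_slope_true(p_hat, p_true)
  }
  wc <- within_cluster_metrics(y, p_hat, p_true, cluster_id)
  structure(list(
    brier = brier_score(y, p_hat),
    c_index_overall = c_index(y, p_hat),
    cal_slope_overall = overall_slope,
    c_index_within_mean = wc$c_index_mean,
    c_index_within_sd = wc$c_index_sd,
    cal_slope_within_mean = wc$cal_slope_mean,
    cal_slope_within_sd = wc$cal_slope_sd,
    n_clusters_excluded = wc$n_clusters_excluded,
    per_cluster = wc$per_cluster), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Brier %.3f | C %.3f | slope %.3f | within C %.3f [%.3f] | within slope %.3f [%.3f]\n",
              x$brier, x$c_index_overall, x$cal_slope_overall,
              x$c_index_within_mean, x$c_index_within_sd,
              x$cal_slope_within_mean, x$cal_slope_within_sd))
  if (x$n_clusters_excluded > 0)
    cat(sprintf("  (%d cluster(s) excluded from within-cluster summaries)\n",
                x$n_clusters_excluded))
  invisible(x)
}

#' Data for calibration plots
#'
#' Per-subject predicted and true risks, grouped by cluster, ready for
#' plotting against the identity line (within a cluster the points trace a
#' monotone curve, one curve per cluster).
#'
#' @param p_hat Predicted risks.
#' @param p_true True latent risks.
#' @param cluster_id Cluster identifiers.
#' @return A data frame with columns `cluster_id`, `p_hat`, `p_true`,
#'   ordered by cluster and predicted risk, with an attribute `reference`
#'   giving the identity line as `c(intercept = 0, slope = 1)`.
#' @export
calibration_plot_data <- function(p_hat, p_true, cluster_id) {
  stopifnot(length(p_hat) == length(p_true),
            length(p_hat) == length(cluster_id))
  df <- data.frame(cluster_id = cluster_id, p_hat = p_hat, p_true = p_true)
  df <- df[order(df$cluster_id, df$p_hat), ]
  rownames(df) <- NULL
  attr(df, "reference") <- c(intercept = 0, slope = 1)
  df
}
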