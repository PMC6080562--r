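#' Convert an intraclass correlation to a random-intercept variance
#'
#' For a logistic random-intercept model the latent-scale residual variance is
#' fixed at \eqn{\pi^2/3}, so an intraclass correlation \eqn{\rho} corresponds
#' to the cluster variance \eqn{\sigma^2_u = \rho \, (\pi^2/3) / (1 - \rho)}.
#'
#' @param icc Intraclass correlation, strictly between 0 and 1.
#' @return The random-intercept variance \eqn{\sigma^2_u}.
#' @seealso [variance_to_icc()]
#' @examples
#' icc_to_variance(0.20) # approximately 0.822
#' @export
icc_to_variance <- function(icc) {
  stopifnot(is.numeric(icc), length(icc) == 1L, is.finite(icc))
  if (icc <= 0 || icc >= 1) stop("`icc` must lie strictly between 0 and 1")
  icc * (pi^2 / 3) / (1 - icc)
}

#' Convert a random-intercept variance to an intraclass correlation
#'
#' @param sigma_u2 Random-intercept variance, strictly positive.
#' @return The intraclass correlation \eqn{\sigma^2_u / (\sigma^2_u + \pi^2/3)}.
#' @seealso [icc_to_variance()]
#' @export
variance_to_icc <- function(sigma_u2) {
  stopifnot(is.numeric(sigma_u2), length(sigma_u2) == 1L, is.finite(sigma_u2))
  if (sigma_u2 <= 0) stop("`sigma_u2` must be strictly positive")
  sigma_u2 / (sigma_u2 + pi^2 / 3)
}

#' Solve the fixed intercept for a target marginal prevalence
#'
#' With x ~ N(0, 1) independent of u ~ N(0, sigma_u2), the linear predictor
#' beyond the intercept collapses to a single normal Z with variance
#' `beta1^2 + sigma_u2`.  The marginal prevalence E\[plogis(beta0 + Z)\] is
#' evaluated by Gauss-Hermite quadrature (64 nodes) and inverted for `beta0`
#' by bracketed root finding.
#'
#' @param beta1 Predictor coefficient.
#' @param sigma_u2 Random-intercept variance (may be 0).
#' @param target_prevalence Desired marginal outcome prevalence in (0, 1).
#' @param n_nodes Number of quadrature nodes.
#' @return The intercept `beta0` such that the marginal prevalence equals
#'   `target_prevalence` to within 1e-6.
#' @examples
#' solve_intercept(1.5, 0.822, 0.5) # 0 by symmetry
#' @export
solve_intercept <- function(beta1, sigma_u2, target_prevalence, n_nodes = 64L) {
  stopifnot(is.finite(beta1), is.finite(sigma_u2), sigma_u2 >= 0)
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("`target_prevalence` must lie strictly between 0 and 1")
  sigma_z <- sqrt(beta1^2 + sigma_u2)
  if (sigma_z == 0) return(qlogis(target_prevalence))
  gh <- lme4::GHrule(n_nodes)
  prevalence <- function(b0) sum(gh[, "w"] * plogis(b0 + sigma_z * gh[, "z"]))
  half <- abs(qlogis(target_prevalence)) + 6 * sigma_z + 1
  stats::uniroot(function(b0) prevalence(b0) - target_prevalence,
                 lower = -half, upper = half, tol = 1e-9)$root
}

#' Simulation configuration for clustered binary-outcome data
#'
#' Describes the generating model: `J` clusters of `n_j` subjects each, one
#' standard-normal predictor with coefficient `beta1`, normal random
#' intercepts with variance `sigma_u2` (or equivalently an `icc` on the
#' latent scale), and a fixed intercept solved so that the marginal outcome
#' prevalence equals `target_prevalence`.  Exactly one of `icc` and
#' `sigma_u2` must be supplied; the other is derived.
#'
#' @param J Number of clusters.
#' @param n_j Subjects per cluster (equal across clusters).
#' @param beta1 True predictor coefficient.
#' @param icc Intraclass correlation in (0, 1); mutually exclusive with
#'   `sigma_u2`.
#' @param sigma_u2 Random-intercept variance; mutually exclusive with `icc`.
#' @param target_prevalence Marginal outcome prevalence in (0, 1).
#' @param seed Master seed; stage-specific substreams are derived from it.
#' @return An object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(J = 50, n_j = 100, beta1 = 1.5, icc = 0.20,
#'                          target_prevalence = 0.5, seed = 1)
#' cfg$sigma_u2
#' @export
simulation_config <- function(J = 50L, n_j = 100L, beta1 = 1.5,
                              icc = NULL, sigma_u2 = NULL,
                              target_prevalence = 0.5, seed = 1L) {
  stopifnot(J >= 1, n_j >= 1, J == round(J), n_j == round(n_j))
  if (is.null(icc) == is.null(sigma_u2))
    stop("supply exactly one of `icc` and `sigma_u2`")
  if (is.null(sigma_u2)) {
    sigma_u2 <- icc_to_variance(icc)
  } else if (sigma_u2 == 0) {
    icc <- 0 # degenerate no-clustering limit, allowed for generation only
  } else {
    icc <- variance_to_icc(sigma_u2)
  }
  stopifnot(sigma_u2 == 0 || abs(icc_to_variance(icc) - sigma_u2) < 1e-10)
  beta0 <- solve_intercept(beta1, sigma_u2, target_prevalence)
  structure(list(J = as.integer(J), n_j = as.integer(n_j), beta1 = beta1,
                 icc = icc, sigma_u2 = sigma_u2, beta0 = beta0,
                 target_prevalence = target_prevalence,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default simulation configuration
#'
#' Fifty clusters of 100 subjects (5000 in total), predictor coefficient 1.5,
#' intraclass correlation 0.20 (cluster variance 0.822) and marginal
#' prevalence 50%.
#'
#' @param seed Master seed.
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `simulation_config`.
#' @export
default_config <- function(seed = 1L, ...) {
  args <- list(J = 50L, n_j = 100L, beta1 = 1.5, icc = 0.20,
               target_prevalence = 0.5, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  if (!is.null(override$sigma_u2)) args$icc <- NULL
  do.call(simulation_config, args)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "simulation_config: J=%d clusters x n_j=%d subjects (n=%d)\n", x$J,
    x$n_j, x$J * x$n_j))
  cat(sprintf("  beta0=%.4f  beta1=%.2f  sigma_u2=%.4f (ICC=%.3f)\n",
              x$beta0, x$beta1, x$sigma_u2, x$icc))
  cat(sprintf("  target prevalence=%.2f  seed=%d\n", x$target_prevalence,
              x$seed))
  invisible(x)
}

#' Generate a clustered binary-outcome dataset
#'
#' Draws subject-level predictors x ~ N(0, 1), cluster random intercepts
#' u_j ~ N(0, sigma_u2), computes the latent risk
#' p = plogis(beta0 + beta1 x + u), and samples y ~ Bernoulli(p).  The
#' `role` selects independent random-number substreams so that a development
#' dataset and a prediction (new-cluster) dataset generated from the same
#' configuration are independent draws from the same population.
#'
#' @param config A [simulation_config()].
#' @param role `"development"` or `"prediction"`.
#' @return A `clustered_dataset`: a data frame with one row per subject and
#'   columns `cluster_id`, `subject_id`, `x`, `y`, plus the simulation truth
#'   `true_u` (cluster random effect) and `true_p` (latent risk).
#' @examples
#' dev <- generate_dataset(default_config(seed = 7), "development")
#' nrow(dev); mean(dev$y)
#' @export
generate_dataset <- function(config, role = c("development", "prediction")) {
  stopifnot(inherits(config, "simulation_config"))
  role <- match.arg(role)
  J <- config$J; n_j <- config$n_j; n <- J * n_j
  cl <- rep(seq_len(J), each = n_j)

  set.seed(substream_seed(config$seed, paste0(role, "-x")))
  x <- rnorm(n)
  set.seed(substream_seed(config$seed, paste0(role, "-u")))
  u <- rnorm(J, 0, sqrt(config$sigma_u2))
  p <- plogis(config$beta0 + config$beta1 * x + u[cl])
  set.seed(substream_seed(config$seed, paste0(role, "-y")))
  y <- rbinom(n, 1L, p)

  clustered_dataset(data.frame(
    cluster_id = cl, subject_id = seq_len(n), x = x, y = y,
    true_u = u[cl], true_p = p))
}

#' Construct or validate a clustered dataset
#'
#' @param df Data frame with columns `cluster_id`, `x`, `y` and optionally
#'   `subject_id`, `true_u`, `true_p`.
#' @return The validated data frame with class `clustered_dataset`.
#' @export
clustered_dataset <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("cluster_id", "x", "y") %in% names(df)))
  if (!all(df$y %in% c(0L, 1L))) stop("`y` must be 0/1")
  if ("true_p" %in% names(df) &&
      any(df$true_p <= 0 | df$true_p >= 1)) stop("`true_p` must lie in (0,1)")
  if (is.null(df$subject_id)) df$subject_id <- seq_len(nrow(df))
  class(df) <- c("clustered_dataset", "data.frame")
  df
}

#' @export
print.clustered_dataset <- function(x, ...) {
  cat(sprintf("clustered_dataset: %d subjects in %d clusters, prevalence %.3f\n",
              nrow(x), length(unique(x$cluster_id)), mean(x$y)))
  NextMethod()
}
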