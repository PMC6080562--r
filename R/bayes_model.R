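#' Weakly informative prior specification
#'
#' Regression coefficients get independent normal priors with a large
#' variance (1000 by default); the random-intercept variance gets an
#' inverse-gamma prior with small shape and rate (0.001 each by default).
#'
#' @param beta_mean Prior mean for `beta0` and `beta1`.
#' @param beta_variance Prior variance for the regression coefficients.
#' @param sigma2_shape,sigma2_rate Inverse-gamma hyperparameters for the
#'   random-intercept variance.
#' @return A `prior_spec`.
#' @export
prior_spec <- function(beta_mean = 0, beta_variance = 1000,
                       sigma2_shape = 0.001, sigma2_rate = 0.001) {
  stopifnot(beta_variance > 0, sigma2_shape > 0, sigma2_rate > 0)
  structure(list(beta_mean = beta_mean, beta_variance = beta_variance,
                 sigma2_shape = sigma2_shape, sigma2_rate = sigma2_rate),
            class = "prior_spec")
}

new_posterior_draws <- function(df, burn_in = NA_integer_,
                                diagnostics = NULL) {
  structure(df,
            burn_in = burn_in,
            thin = if (nrow(df)) diff(df$iteration)[1] else NA_integer_,
            diagnostics = diagnostics,
            class = c("posterior_draws", "data.frame"))
}

#' Posterior sampling for the random-intercept logistic model
#'
#' Gibbs sampler using Polya-Gamma data augmentation: the Bernoulli-logit
#' likelihood is augmented with PG(1, lp) latent variables, making the full
#' conditionals for the regression coefficients and the cluster intercepts
#' Gaussian and the conditional for the random-intercept variance
#' inverse-gamma.  No tuning is required and runs are reproducible from the
#' seed.  Chains are initialized at the plain logistic-regression estimates
#' with all random intercepts at 0 and variance 1.
#'
#' @param data A `clustered_dataset` (model development data).
#' @param priors A [prior_spec()].
#' @param chains Number of chains.
#' @param thin Thinning interval: every `thin`-th post-burn-in iteration is
#'   saved.
#' @param n_save Saved iterations per chain (total draws =
#'   `chains * n_save`).
#' @param burn_in Burn-in iterations discarded before thinning starts.
#' @param seed Master seed; each chain runs on its own substream.
#' @return A `posterior_draws` data frame with columns `chain`, `iteration`,
#'   `beta0`, `beta1`, `sigma_u2`, and attributes `burn_in`, `thin` and
#'   `diagnostics` (potential scale reduction factors when `chains >= 2`).
#' @examples
#' \donttest{
#' dev <- generate_dataset(default_config(seed = 3, J = 10, n_j = 30))
#' draws <- run_mcmc(dev, burn_in = 500, seed = 3)
#' summary(draws$beta1)
#' }
#' @export
run_mcmc <- function(data, priors = prior_spec(), chains = 2L, thin = 10L,
                     n_save = 100L, burn_in = 5000L, seed = 1L) {
  stopifnot(inherits(data, "clustered_dataset"), chains >= 1L, thin >= 1L,
            n_save >= 1L, burn_in >= 0L)
  if (priors$beta_mean != 0)
    stop("the sampler assumes a zero prior mean for the coefficients")
  clusters <- sort(unique(data$cluster_id))
  cl0 <- match(data$cluster_id, clusters) - 1L

  init <- coef(glm(y ~ x, binomial("logit"), data = data))

  out <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(substream_seed(seed, paste0("mcmc-chain-", ch)))
    res <- pg_gibbs_chain(
      as.integer(data$y), data$x, cl0, length(clusters),
      init[1], init[2], priors$beta_variance, priors$sigma2_shape,
      priors$sigma2_rate, as.integer(burn_in), as.integer(thin),
      as.integer(n_save))
    out[[ch]] <- data.frame(chain = ch,
                            iteration = burn_in + thin * seq_len(n_save),
                            res$draws)
  }
  draws <- new_posterior_draws(do.call(rbind, out), burn_in = burn_in)
  if (chains >= 2L) {
    diag <- check_convergence(draws)
    attr(draws, "diagnostics") <- diag
    if (!diag$pass)
      warning("potential scale reduction factor >= 1.1 for: ",
              paste(names(diag$psrf)[diag$psrf >= 1.1], collapse = ", "))
  }
  draws
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %d draws (%d chain(s), thin %s, burn-in %s)\n",
              nrow(x), length(unique(x$chain)), attr(x, "thin"),
              attr(x, "burn_in")))
  for (p in c("beta0", "beta1", "sigma_u2"))
    cat(sprintf("  %-9s median %.4f  95%% CrI [%.4f, %.4f]\n", p,
                median(x[[p]]), quantile(x[[p]], 0.025),
                quantile(x[[p]], 0.975)))
  diag <- attr(x, "diagnostics")
  if (!is.null(diag))
    cat("  PSRF:", paste(sprintf("%s=%.3f", names(diag$psrf), diag$psrf),
                         collapse = " "), "\n")
  invisible(x)
}

#' Gelman-Rubin convergence check
#'
#' Computes the potential scale reduction factor (PSRF) for each model
#' parameter from two or more chains; values below 1.1 for all parameters
#' are taken as compatible with convergence.
#'
#' @param draws A `posterior_draws` object with at least two chains.
#' @return A list with `psrf` (named vector) and `pass` (logical).
#' @export
check_convergence <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  chains <- unique(draws$chain)
  if (length(chains) < 2L) stop("need at least 2 chains for the PSRF")
  psrf <- vapply(c("beta0", "beta1", "sigma_u2"), function(p) {
    by_chain <- split(draws[[p]], draws$chain)
    n <- length(by_chain[[1]])
    w <- mean(vapply(by_chain, var, 0))
    b_over_n <- var(vapply(by_chain, mean, 0))
    sqrt(((n - 1) / n * w + b_over_n) / w)
  }, 0)
  list(psrf = psrf, pass = all(psrf < 1.1))
}
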