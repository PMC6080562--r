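#' Fit the random-intercept logistic model by maximum likelihood
#'
#' Estimates `logit(p) = beta0 + beta1 x + u_cluster` with u ~ N(0, sigma_u2)
#' by maximizing the marginal likelihood, integrating the random intercept
#' out with adaptive Gauss-Hermite quadrature (via [lme4::glmer()]).  When a
#' per-cluster expert-category covariate is supplied, its dummies enter the
#' linear predictor as fixed effects alongside the retained random intercept
#' (the FREQ.2/3/5 model variants).
#'
#' @param data A `clustered_dataset`.
#' @param expert_covariate Optional per-cluster integer category codes as
#'   produced by [encode_expert_categories()] (one per development cluster in
#'   cluster-id order, with a `reference` attribute).
#' @param n_quadrature Number of adaptive quadrature nodes.
#' @return A `freq_fit` with elements `beta0_hat`, `beta1_hat`,
#'   `sigma_u2_hat`, `category_coefs` (named by region index, reference level
#'   omitted), `loglik`, `converged`, `n_quadrature`, and the underlying
#'   `lme4` fit as `fit`.
#' @examples
#' dev <- generate_dataset(default_config(seed = 3, J = 10, n_j = 30))
#' fit <- fit_glmm_ml(dev)
#' c(fit$beta0_hat, fit$beta1_hat, fit$sigma_u2_hat)
#' @export
fit_glmm_ml <- function(data, expert_covariate = NULL, n_quadrature = 15L) {
  stopifnot(inherits(data, "clustered_dataset"))
  clusters <- sort(unique(data$cluster_id))
  if (length(clusters) < 2L) stop("need at least 2 clusters")
  if (length(unique(data$y)) < 2L) stop("outcome is constant")

  df <- data.frame(y = data$y, x = data$x,
                   cluster = factor(data$cluster_id, levels = clusters))
  formula <- y ~ x + (1 | cluster)
  if (!is.null(expert_covariate)) {
    stopifnot(length(expert_covariate) == length(clusters))
    ref <- attr(expert_covariate, "reference")
    if (is.null(ref)) stop("`expert_covariate` lacks a `reference` attribute")
    codes <- expert_covariate[match(data$cluster_id, clusters)]
    df$expert_cat <- stats::relevel(factor(codes), ref = as.character(ref))
    formula <- y ~ x + expert_cat + (1 | cluster)
  }

  warn <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(formula, data = df, family = binomial("logit"),
                nAGQ = n_quadrature),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  fe <- lme4::fixef(fit)
  category_coefs <- NULL
  if (!is.null(expert_covariate)) {
    idx <- grep("^expert_cat", names(fe))
    category_coefs <- setNames(fe[idx], sub("^expert_cat", "", names(fe)[idx]))
    attr(category_coefs, "reference") <- attr(expert_covariate, "reference")
    attr(category_coefs, "m") <- attr(expert_covariate, "m") %||%
      length(unique(expert_covariate))
  }
  if (any(abs(fe) > 15))
    warning("very large coefficient(s) suggest separation: ",
            paste(sprintf("%s=%.1f", names(fe), fe)[abs(fe) > 15],
                  collapse = ", "))

  conv <- length(fit@optinfo$conv$lme4$messages) == 0 &&
    fit@optinfo$conv$opt == 0
  if (!conv) warning("maximum-likelihood fit did not converge cleanly")

  structure(list(
    beta0_hat = unname(fe["(Intercept)"]),
    beta1_hat = unname(fe["x"]),
    sigma_u2_hat = unname(lme4::VarCorr(fit)$cluster[1, 1]),
    category_coefs = category_coefs,
    loglik = as.numeric(logLik(fit)),
    converged = conv,
    n_quadrature = as.integer(n_quadrature),
    warnings = warn,
    fit = fit), class = "freq_fit")
}

#' @export
print.freq_fit <- function(x, ...) {
  cat(sprintf(
    "freq_fit: beta0=%.4f beta1=%.4f sigma_u2=%.4f (logLik %.1f, %s)\n",
    x$beta0_hat, x$beta1_hat, x$sigma_u2_hat, x$loglik,
    if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$category_coefs)) {
    cat("  expert category coefficients (reference ",
        attr(x$category_coefs, "reference"), "):\n", sep = "")
    print(round(x$category_coefs, 4))
  }
  invisible(x)
}

#' Frequentist prediction with the new-cluster random effect set to zero
#'
#' Computes `plogis(beta0_hat + beta1_hat x)` for subjects in new clusters,
#' replacing the unknown random effect with its mean 0.  For the FREQ.2/3/5
#' variants, the expert-category dummy coefficient for each new cluster's
#' category is added to the linear predictor.
#'
#' @param fit A `freq_fit`.
#' @param new_data A `clustered_dataset` of new-cluster subjects.
#' @param expert_categories Optional per-cluster category codes for the new
#'   clusters (in sorted cluster-id order), required iff the model was fitted
#'   with an expert covariate.
#' @return Numeric vector of predicted risks, one per row of `new_data`.
#' @export
predict_freq <- function(fit, new_data, expert_categories = NULL) {
  stopifnot(inherits(fit, "freq_fit"), inherits(new_data, "clustered_dataset"))
  if (!fit$converged) warning("predicting from a fit flagged as non-converged")
  lp <- fit$beta0_hat + fit$beta1_hat * new_data$x
  if (!is.null(fit$category_coefs)) {
    if (is.null(expert_categories))
      stop("model includes an expert covariate; supply `expert_categories`")
    clusters <- sort(unique(new_data$cluster_id))
    stopifnot(length(expert_categories) == length(clusters))
    ref <- attr(fit$category_coefs, "reference")
    coefs <- c(setNames(0, as.character(ref)), fit$category_coefs)
    codes <- as.character(expert_categories[match(new_data$cluster_id, clusters)])
    if (!all(codes %in% names(coefs)))
      stop("new cluster category code(s) unknown to the model: ",
           paste(setdiff(unique(codes), names(coefs)), collapse = ", "))
    lp <- lp + coefs[codes]
  } else if (!is.null(expert_categories)) {
    stop("`expert_categories` supplied but the model has no expert covariate")
  }
  unname(plogis(lp))
}

#' Encode cluster random effects as expert-opinion categories
#'
#' Places each cluster's true random effect in the empirical quantile bins
#' (halves, tertiles or quintiles) of the development clusters' random
#' effects.  The reference category used when the codes enter a model as
#' dummies follows the package convention: lower half for m = 2, second tertile
#' for m = 3, third quintile for m = 5.  Values falling exactly on a bin
#' boundary are assigned to the lower bin.
#'
#' @param true_u Random effects of the clusters to encode.
#' @param dev_u Random effects of the development clusters defining the
#'   empirical quantiles.
#' @param m Number of categories: 2, 3 or 5.
#' @return Integer codes in 1..m with attributes `reference` and `m`.
#' @examples
#' set.seed(1); devu <- rnorm(50)
#' table(encode_expert_categories(devu, devu, m = 5))
#' @export
encode_expert_categories <- function(true_u, dev_u, m) {
  stopifnot(m %in% c(2L, 3L, 5L), length(dev_u) >= 1)
  breaks <- quantile(dev_u, probs = seq_len(m - 1) / m, names = FALSE)
  codes <- as.integer(cut(true_u, c(-Inf, breaks, Inf), labels = FALSE,
                          right = TRUE))
  ref <- unname(c(`2` = 1L, `3` = 2L, `5` = 3L)[as.character(m)])
  structure(codes, reference = ref, m = as.integer(m))
}
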