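# Small configurations and datasets shared across test files.  Everything is
# generated in code under fixed seeds; nothing is read from disk.

tiny_config <- function(seed = 11, ...) {
  default_config(seed = seed, J = 10L, n_j = 30L, ...)
}

small_config <- function(seed = 11, ...) {
  default_config(seed = seed, J = 20L, n_j = 50L, ...)
}

# fast MCMC settings for unit tests (not the scenario defaults)
fast_mcmc <- list(chains = 2L, thin = 2L, n_save = 50L, burn_in = 300L)

# hand-built posterior draws with prescribed parameter values
fake_draws <- function(beta0, beta1, sigma_u2, chains = 1L) {
  K <- max(length(beta0), length(beta1), length(sigma_u2))
  df <- data.frame(chain = rep(seq_len(chains), length.out = K),
                   iteration = seq_len(K),
                   beta0 = rep_len(beta0, K), beta1 = rep_len(beta1, K),
                   sigma_u2 = rep_len(sigma_u2, K))
  clustpred:::new_posterior_draws(df)
}

# minimal new-cluster dataset: one subject per x value in each of C clusters
fake_newdata <- function(x, C = 1L) {
  clustered_dataset(data.frame(
    cluster_id = rep(seq_len(C), each = length(x)),
    x = rep(x, C), y = rep_len(c(0L, 1L), length(x) * C)))
}
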