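#' Read and write clustered datasets as CSV
#'
#' Datasets are exchanged as UTF-8 CSV with a header and columns
#' `cluster_id`, `subject_id`, `x`, `y`, plus the optional truth columns
#' `true_u` and `true_p` for simulated data.
#'
#' @param data A `clustered_dataset`.
#' @param path File path.
#' @return `read_dataset_csv` returns a `clustered_dataset`;
#'   `write_dataset_csv` returns `path` invisibly.
#' @export
write_dataset_csv <- function(data, path) {
  stopifnot(inherits(data, "clustered_dataset"))
  write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  clustered_dataset(read.csv(path))
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file must contain fields named as in [simulation_config()]: `J`,
#' `n_j`, `beta1`, one of `icc` / `sigma_u2`, `target_prevalence`, `seed`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `simulation_config`.
#' @export
read_config <- function(path) {
  fields <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- c("J", "n_j", "beta1", "icc", "sigma_u2", "target_prevalence",
               "seed")
  unknown <- setdiff(names(fields), allowed)
  if (length(unknown))
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  do.call(simulation_config, fields)
}

#' Serialize posterior draws to CSV
#'
#' One row per saved iteration with columns `chain`, `iteration`, `beta0`,
#' `beta1`, `sigma_u2` (the layout of an MCMC output table).
#'
#' @param draws A `posterior_draws` object from [run_mcmc()].
#' @param path File path.
#' @return `read_draws_csv` returns a `posterior_draws`;
#'   `write_draws_csv` returns `path` invisibly.
#' @export
write_draws_csv <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  write.csv(as.data.frame(draws), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_draws_csv
#' @export
read_draws_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("chain", "iteration", "beta0", "beta1", "sigma_u2") %in%
                  names(df)))
  new_posterior_draws(df)
}
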