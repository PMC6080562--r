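#' Bounds of an equal-probability region of the random-effects distribution
#'
#' The N(0, sigma_u^2) random-effects distribution is divided into `m`
#' regions of equal probability 1/m; region `r` covers standard-normal
#' probabilities ((r-1)/m, r/m).  The bounds scale linearly with `sigma_u`,
#' so a region statement ("this cluster is in the lowest fifth") is
#' meaningful for any value of the random-effects standard deviation.
#'
#' @param r Region index in 1..m.
#' @param m Number of regions.
#' @param sigma_u Random-effects standard deviation.
#' @return Numeric vector `c(lower, upper)`; `-Inf` / `Inf` for the outer
#'   regions.
#' @examples
#' region_bounds(1, 2, 1)        # lower half: (-Inf, 0)
#' region_bounds(2, 3, 1)        # middle third
#' @export
region_bounds <- function(r, m, sigma_u) {
  stopifnot(m >= 1, m == round(m), sigma_u > 0)
  if (r < 1 || r > m || r != round(r)) stop("`r` must be an integer in 1..m")
  sigma_u * qnorm(c((r - 1) / m, r / m))
}

#' Optimal expert judgment: the region containing the true random effect
#'
#' An optimal (simulated) expert selects, on a scale of `m` equal-probability
#' regions, the region of the random-effects distribution that contains the
#' cluster's true random effect: region `ceiling(m * pnorm(true_u / sigma_u))`.
#'
#' @param true_u True random effect(s), vectorized.
#' @param sigma_u_true Standard deviation of the generating random-effects
#'   distribution.
#' @param m Number of regions (the built-in designs use 2, 3 or 5; any m >= 1 is accepted).
#' @return Integer region indices in 1..m.
#' @export
elicit_optimal <- function(true_u, sigma_u_true, m) {
  stopifnot(sigma_u_true > 0, m >= 1, m == round(m))
  r <- ceiling(m * pnorm(true_u / sigma_u_true))
  as.integer(pmin(pmax(r, 1L), m))
}

#' Discrepant expert judgment: an adjacent region
#'
#' A discrepant expert selects a region next to the one containing the true
#' value: edge regions have a single neighbor, interior regions yield the
#' left or right neighbor with equal probability.  Uses the current RNG
#' state; seed the caller for reproducibility.
#'
#' @param optimal_region Region index(es) the optimal expert would choose.
#' @param m Number of regions; must be >= 2.
#' @return Integer region indices, never equal to `optimal_region`.
#' @export
elicit_discrepant <- function(optimal_region, m) {
  stopifnot(m == round(m))
  if (m < 2) stop("no adjacent region exists when m = 1")
  if (any(optimal_region < 1 | optimal_region > m))
    stop("`optimal_region` out of range 1..m")
  coin <- ifelse(runif(length(optimal_region)) < 0.5, -1L, 1L)
  step <- ifelse(optimal_region == 1L, 1L,
                 ifelse(optimal_region == m, -1L, coin))
  as.integer(optimal_region + step)
}

#' Randomly select the clusters that receive discrepant expert opinion
#'
#' @param cluster_ids Vector of cluster identifiers.
#' @param pct Proportion of clusters to select, in \[0, 1\] (0.10, 0.30 or
#'   0.50 in the built-in designs).
#' @return A subset of `cluster_ids` of size `round(pct * length(cluster_ids))`,
#'   sampled uniformly without replacement.
#' @export
assign_discrepant_clusters <- function(cluster_ids, pct) {
  if (pct < 0 || pct > 1) stop("`pct` must lie in [0, 1]")
  k <- round(pct * length(cluster_ids))
  if (k == 0) return(cluster_ids[0])
  sort(sample(cluster_ids, k, replace = FALSE))
}

#' Simulate a full set of per-cluster expert judgments
#'
#' For each new cluster, the optimal region (the one containing the true
#' random effect, judged against the true generating standard deviation) is
#' elicited; clusters listed in `discrepant_clusters` instead receive an
#' adjacent region.
#'
#' @param cluster_ids New-cluster identifiers (one judgment per cluster).
#' @param true_u True random effects, aligned with `cluster_ids`.
#' @param sigma_u_true True random-effects standard deviation.
#' @param m Scale: 2, 3 or 5 regions.
#' @param discrepant_clusters Cluster ids that receive discrepant opinion.
#' @return An `expert_judgments` data frame with columns `cluster_id`, `m`,
#'   `region`, `discrepant`.
#' @export
elicit_judgments <- function(cluster_ids, true_u, sigma_u_true, m,
                             discrepant_clusters = NULL) {
  stopifnot(length(cluster_ids) == length(true_u),
            !anyDuplicated(cluster_ids))
  region <- elicit_optimal(true_u, sigma_u_true, m)
  disc <- cluster_ids %in% discrepant_clusters
  if (any(disc)) region[disc] <- elicit_discrepant(region[disc], m)
  structure(data.frame(cluster_id = cluster_ids, m = as.integer(m),
                       region = region, discrepant = disc),
            class = c("expert_judgments", "data.frame"))
}
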