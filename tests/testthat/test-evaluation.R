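test_that("Brier score is the mean squared prediction error", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(c(1, 0), c(0.5, 0.5)), 0.25)
  expect_equal(brier_score(c(1, 0, 1), c(0.8, 0.2, 0.6)), 0.08)
  set.seed(1)
  y <- rbinom(40, 1, 0.5)
  expect_equal(brier_score(y, rep(0.5, 40)), 0.25) # exact for any outcome
  expect_error(brier_score(c(1, 0), 0.5), "differ in length")
})

test_that("C-index equals Mann-Whitney concordance with 0.5 tie credit", {
  expect_equal(c_index(c(0, 0, 1, 1), c(0.1, 0.2, 0.7, 0.9)), 1)
  expect_equal(c_index(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  expect_equal(c_index(c(0, 0, 1, 1), c(0.1, 0.4, 0.3, 0.8)), 0.75)
  expect_error(c_index(c(1, 1), c(0.2, 0.3)), "one outcome class")

  # exhaustive pair-enumeration oracle, including ties
  oracle <- function(y, s) {
    num <- 0; den <- 0
    for (i in which(y == 1)) for (j in which(y == 0)) {
      den <- den + 1
      num <- num + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    }
    num / den
  }
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5)) # both classes guaranteed
    s <- round(runif(n), 1)              # coarse scores force ties
    expect_equal(c_index(y, s), oracle(y, s))
  }
})

test_that("calibration slope against true risks is the OLS slope", {
  p <- seq(0.1, 0.9, by = 0.1)
  expect_equal(calibration_slope_true(p, p), 1)
  expect_equal(calibration_slope_true(p, 0.1 + 0.7 * p), 0.7)
  set.seed(8)
  ph <- runif(50); pt_ <- plogis(qlogis(ph) + rnorm(50, 0, 0.3))
  expect_equal(calibration_slope_true(ph, pt_),
               stats::cov(ph, pt_) / var(ph), tolerance = 1e-12)
  expect_error(calibration_slope_true(rep(0.4, 9), p), "constant")
})

test_that("calibration slope against observed outcomes is the logistic slope", {
  set.seed(9)
  lp <- rnorm(1e5, 0, 1.2)
  y <- rbinom(length(lp), 1, plogis(lp))
  s <- calibration_slope_observed(y, lp)
  expect_lt(abs(as.numeric(s) - 1), 0.05)
  # rescaling the linear predictor rescales the slope exactly reciprocally
  s2 <- calibration_slope_observed(y, 2 * lp)
  expect_equal(as.numeric(s2), as.numeric(s) / 2, tolerance = 1e-8)
  expect_error(calibration_slope_observed(y, rep(1, length(y))), "constant")
  expect_error(calibration_slope_observed(rep(1L, 10), rnorm(10)),
               "single outcome class")
})

test_that("within-cluster metrics summarize per cluster and count exclusions", {
  set.seed(10)
  n <- 40
  one <- data.frame(x = runif(n))
  one$p <- plogis(qlogis(one$x) * 0.8)
  one$y <- c(0, 1, rbinom(n - 2, 1, 0.5))
  # five identical copies of one cluster: zero spread across clusters
  five <- do.call(rbind, lapply(1:5, function(k) cbind(one, cluster = k)))
  wc <- within_cluster_metrics(five$y, five$x, five$p, five$cluster)
  expect_equal(wc$c_index_sd, 0)
  expect_equal(wc$cal_slope_sd, 0, tolerance = 1e-12)
  expect_equal(wc$c_index_mean, c_index(one$y, one$x))
  expect_equal(wc$n_clusters_excluded, 0)

  # an all-cases cluster is excluded from the C-index and counted
  allcase <- data.frame(x = runif(10), p = runif(10), y = 1L, cluster = 6)
  names(allcase) <- names(five)
  six <- rbind(five, allcase)
  wc6 <- within_cluster_metrics(six$y, six$x, six$p, six$cluster)
  expect_equal(wc6$n_clusters_excluded, 1)
  expect_true(is.na(wc6$per_cluster$c_index[6]))
  expect_equal(wc6$c_index_mean, wc$c_index_mean)
})

test_that("overall metrics ignore subject order and cluster labels", {
  dat <- generate_dataset(tiny_config(seed = 25), "prediction")
  p_hat <- plogis(-0.1 + 1.2 * dat$x)
  rep1 <- metrics_report(dat$y, p_hat, dat$true_p, dat$cluster_id)
  perm <- sample(nrow(dat))
  relabel <- c(4, 9, 1, 7, 2, 10, 3, 6, 5, 8)[dat$cluster_id]
  rep2 <- metrics_report(dat$y[perm], p_hat[perm], dat$true_p[perm],
                         relabel[perm])
  for (f in c("brier", "c_index_overall", "cal_slope_overall",
              "c_index_within_mean", "c_index_within_sd",
              "cal_slope_within_mean", "cal_slope_within_sd"))
    expect_equal(rep1[[f]], rep2[[f]], tolerance = 1e-12)
})

test_that("metrics_report switches calibration mode with the truth", {
  dat <- generate_dataset(tiny_config(seed = 26), "prediction")
  p_hat <- plogis(0.1 + 0.9 * qlogis(dat$true_p))
  sim <- metrics_report(dat$y, p_hat, dat$true_p, dat$cluster_id)
  expect_equal(sim$cal_slope_overall,
               calibration_slope_true(p_hat, dat$true_p))
  emp <- metrics_report(dat$y, p_hat, NULL, dat$cluster_id)
  expect_equal(emp$cal_slope_overall,
               as.numeric(calibration_slope_observed(dat$y, qlogis(p_hat))))
  expect_true(is.na(emp$cal_slope_within_mean))
})

test_that("calibration plot data traces one monotone curve per cluster", {
  dat <- generate_dataset(tiny_config(seed = 27), "prediction")
  p_hat <- plogis(-0.4 + 1.1 * dat$x) # cluster-free monotone predictions
  cp <- calibration_plot_data(p_hat, dat$true_p, dat$cluster_id)
  expect_equal(nrow(cp), nrow(dat))
  expect_equal(attr(cp, "reference"), c(intercept = 0, slope = 1))
  # within each cluster true risk is monotone in the predicted risk
  for (cl in unique(cp$cluster_id)) {
    sub <- cp[cp$cluster_id == cl, ]
    expect_true(all(diff(sub$p_hat) >= 0)) # sorted output
    expect_true(all(diff(sub$p_true) > 0))
  }
  perfect <- calibration_plot_data(dat$true_p, dat$true_p, dat$cluster_id)
  expect_equal(perfect$p_hat, perfect$p_true)
})
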