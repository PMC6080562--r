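test_that("predicted risk is the inverse-logit of the full linear predictor", {
  expect_equal(predicted_risk(0, 0, 0, 2.3), 0.5)
  expect_equal(predicted_risk(-1.35, 1.07, 0.50, 1.1),
               plogis(-1.35 + 1.07 * 1.1 + 0.50), tolerance = 1e-12)
  # overflow safety at extreme linear predictors
  expect_equal(predicted_risk(0, 1, 0, 1000), 1)
  expect_equal(predicted_risk(0, 1, 0, -1000), 0)
  expect_error(predicted_risk(NA, 1, 0, 1))
})

test_that("the point prediction is the empirical median of the draws", {
  expect_equal(summarize_point(rep(0.3, 7)), 0.3)
  expect_equal(summarize_point(c(0.1, 0.2, 0.3, 0.4)), 0.25)
  set.seed(40)
  draws <- runif(200)
  s <- sort(draws) # sort-based oracle, midpoint convention for even K
  expect_equal(summarize_point(draws), (s[100] + s[101]) / 2)
  expect_error(summarize_point(numeric(0)), "empty")
})

test_that("weakly informative prediction draws fresh cluster effects per iteration", {
  dr <- fake_draws(beta0 = rnorm(100, -1, 0.1), beta1 = rnorm(100, 1, 0.1),
                   sigma_u2 = exp(rnorm(100, 0, 0.2)))
  nd <- fake_newdata(c(-1, 0, 1), C = 4L)
  a <- predict_bayes_weakly(dr, nd, seed = 2)
  b <- predict_bayes_weakly(dr, nd, seed = 2)
  expect_identical(a$risk_draws, b$risk_draws)
  expect_false(identical(a$risk_draws,
                         predict_bayes_weakly(dr, nd, seed = 3)$risk_draws))
  expect_equal(dim(a$risk_draws), c(12L, 100L))
  expect_equal(dim(a$u_draws), c(4L, 100L))
  expect_true(all(a$risk_draws > 0 & a$risk_draws < 1))
  expect_equal(a$risk_point, unname(apply(a$risk_draws, 1, median)))
  # all subjects of one cluster share that cluster's u draws
  expect_equal(a$risk_draws[1, ],
               plogis(dr$beta0 + dr$beta1 * -1 + a$u_draws[1, ]))

  # degenerate variance: reduces to plugging in the (beta0, beta1) draws
  dr0 <- fake_draws(beta0 = rnorm(50), beta1 = rnorm(50), sigma_u2 = 0)
  p0 <- predict_bayes_weakly(dr0, fake_newdata(0.7), seed = 1)
  expect_equal(p0$risk_point, median(plogis(dr0$beta0 + dr0$beta1 * 0.7)))

  # CLT bound on the mean of the cluster-effect draws at constant variance 1
  drc <- fake_draws(beta0 = 0, beta1 = 0, sigma_u2 = rep(1, 1e4))
  w <- predict_bayes_weakly(drc, fake_newdata(0), seed = 9)
  expect_lt(abs(mean(w$u_draws)), 0.03)
})

test_that("truncated prediction honors the expert regions exactly", {
  K <- 200L
  dr <- fake_draws(beta0 = rnorm(K, -1, 0.1), beta1 = rnorm(K, 1.5, 0.1),
                   sigma_u2 = exp(rnorm(K, -0.2, 0.3)))
  nd <- fake_newdata(seq(-2, 2, by = 0.5), C = 5L)
  judg <- data.frame(cluster_id = 1:5, m = 5L, region = c(1L, 2L, 3L, 4L, 5L),
                     discrepant = FALSE)
  res <- predict_bayes_truncated(dr, nd, judg, seed = 4)
  expect_equal(res$model, "BAYES.HI")
  # every cluster-effect draw lies inside its region for its own sigma draw
  for (c in 1:5) {
    bounds <- vapply(sqrt(dr$sigma_u2), function(s)
      region_bounds(judg$region[c], 5L, s), numeric(2))
    expect_true(all(res$u_draws[c, ] > bounds[1, ] &
                      res$u_draws[c, ] < bounds[2, ]))
  }
  # higher region => stochastically larger cluster effects
  expect_true(all(diff(rowMeans(res$u_draws)) > 0))

  # m = 1 degenerate scale reproduces the weakly informative draws exactly
  j1 <- data.frame(cluster_id = 1:5, m = 1L, region = 1L, discrepant = FALSE)
  t1 <- predict_bayes_truncated(dr, nd, j1, seed = 4, model = "BAYES.WI")
  w1 <- predict_bayes_weakly(dr, nd, seed = 4)
  expect_identical(t1$risk_draws, w1$risk_draws)

  expect_error(predict_bayes_truncated(dr, nd, judg[-2, ], seed = 1),
               "missing expert judgment")
  bad <- judg; bad$region[1] <- 6L
  expect_error(predict_bayes_truncated(dr, nd, bad, seed = 1),
               "incompatible")
  mixed <- judg; mixed$m[1] <- 3L
  expect_error(predict_bayes_truncated(dr, nd, mixed, seed = 1),
               "one scale")
})

test_that("truncated sampling matches the analytic truncated-normal law", {
  K <- 1e5L
  # half-normal check: lower half at sigma = 1 has mean -sqrt(2/pi)
  dr <- fake_draws(beta0 = 0, beta1 = 0, sigma_u2 = rep(1, K))
  j <- data.frame(cluster_id = 1L, m = 2L, region = 1L, discrepant = FALSE)
  res <- predict_bayes_truncated(dr, fake_newdata(0), j, seed = 6)
  expect_lt(abs(mean(res$u_draws) + sqrt(2 / pi)), 0.01)
  expect_true(all(res$u_draws < 0))

  # Kolmogorov-Smirnov against the exact law on the probability scale:
  # region 2 of 5 maps to pnorm(u) uniform on (0.2, 0.4)
  j2 <- data.frame(cluster_id = 1L, m = 5L, region = 2L, discrepant = FALSE)
  res2 <- predict_bayes_truncated(dr, fake_newdata(0), j2, seed = 7)
  ks <- suppressWarnings(stats::ks.test(pnorm(as.numeric(res2$u_draws)),
                                        "punif", 0.2, 0.4))
  expect_gt(ks$p.value, 0.01)
})

test_that("positive slope draws make within-cluster rankings follow the predictor", {
  dat <- generate_dataset(tiny_config(seed = 19))
  draws <- do.call(run_mcmc, c(list(dat, seed = 19), fast_mcmc))
  expect_true(all(draws$beta1 > 0))
  nd <- generate_dataset(tiny_config(seed = 19), "prediction")
  res <- predict_bayes_weakly(draws, nd, seed = 19)
  for (cl in unique(nd$cluster_id)) {
    i <- nd$cluster_id == cl
    expect_equal(order(res$risk_point[i]), order(nd$x[i]))
  }
})

test_that("prediction tables carry the point predictions and optional draws", {
  dr <- fake_draws(beta0 = rnorm(10), beta1 = rnorm(10), sigma_u2 = 1)
  res <- predict_bayes_weakly(dr, fake_newdata(c(0, 1), C = 2L), seed = 1)
  tab <- prediction_table(res)
  expect_equal(names(tab), c("model", "cluster_id", "x", "risk_point"))
  expect_equal(nrow(tab), 4L)
  wide <- prediction_table(res, draws = TRUE)
  expect_equal(ncol(wide), 4L + 10L)
  expect_equal(unname(as.matrix(wide[, -(1:4)])), unname(res$risk_draws))
})
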