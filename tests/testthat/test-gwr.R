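test_that("kernel weights match their closed forms", {
  coords <- rbind(c(0, 0), c(300, 400), c(1000, 0))  # d = 0, 500, 1000
  w <- kernel_weights(coords, 1, bandwidth = 1000, kernel = "bisquare",
                      adaptive = FALSE)
  expect_equal(w, c(1, (1 - 0.25)^2, 0))  # d = b/2 -> 0.5625; d >= b -> 0
  expect_equal(w[2], 0.5625)
  wg <- kernel_weights(coords, 1, bandwidth = 1000, kernel = "gaussian",
                       adaptive = FALSE)
  expect_equal(wg, exp(-0.5 * (c(0, 500, 1000) / 1000)^2))
  # adaptive: scale is the distance to the k-th nearest neighbour
  wa <- kernel_weights(coords, 1, bandwidth = 2, kernel = "bisquare",
                       adaptive = TRUE)
  expect_equal(wa, c(1, 0, 0))  # b = 500, the 2nd neighbour itself drops out
})

test_that("local fits solve the weighted normal equations", {
  # unweighted limit equals global OLS
  set.seed(1)
  X <- cbind(1, runif(20), rnorm(20))
  y <- X %*% c(1, 2, -1) + rnorm(20)
  loc <- fit_local(X, y, rep(1, 20))
  expect_equal(unname(loc$beta), unname(qr.solve(X, y)[, 1]),
               tolerance = 1e-10)

  # 5-point hand-checkable system
  X5 <- cbind(1, c(0, 1, 2, 3, 4))
  y5 <- c(1, 3, 2, 5, 4)
  w5 <- c(1, 0.8, 0.6, 0.4, 0.2)
  loc5 <- fit_local(X5, y5, w5)
  expect_equal(unname(loc5$beta), oracle_wls(X5, y5, w5), tolerance = 1e-10)

  # constant response: zero slopes, intercept at the constant
  locc <- fit_local(X, rep(3.5, 20), runif(20, 0.1, 1))
  expect_equal(unname(locc$beta), c(3.5, 0, 0), tolerance = 1e-8)

  # rank deficiency is flagged as NULL, not an error
  Xbad <- cbind(1, 1:5, 2 * (1:5))
  expect_null(fit_local(Xbad, rnorm(5), rep(1, 5)))
})

test_that("gwr rows agree with standalone local fits", {
  des <- random_design(25, p = 3, seed = 42)
  fit <- fit_gwr(des, "bisquare", bandwidth = 12, adaptive = TRUE)
  for (i in c(1, 9, 25)) {
    w <- kernel_weights(des$coords, i, 12, "bisquare", adaptive = TRUE)
    loc <- fit_local(des$X, des$y, w)
    expect_equal(unname(fit$local_beta[i, ]), unname(loc$beta),
                 tolerance = 1e-10)
  }
  expect_true(fit$hat_trace >= 1 && fit$hat_trace <= fit$n)
  expect_true(fit$rss >= 0)
  ok <- fit$local_se > 0 & !is.na(fit$local_se)
  expect_equal(fit$local_t[ok], (fit$local_beta / fit$local_se)[ok])
})

test_that("huge bandwidth collapses gwr onto the global fit", {
  des <- random_design(30, p = 3, seed = 7)
  gb <- qr.solve(des$X, des$y)
  maxd <- max(dist(des$coords))
  fit <- fit_gwr(des, "gaussian", bandwidth = 1e5 * maxd, adaptive = FALSE)
  expect_lt(max(abs(sweep(fit$local_beta, 2, gb))), 1e-8)
  expect_equal(fit$effective_params, ncol(des$X), tolerance = 1e-6)
  # monotone convergence beyond the largest pairwise distance
  devs <- vapply(c(1, 10, 100), function(m) {
    f <- fit_gwr(des, "gaussian", bandwidth = m * maxd, adaptive = FALSE)
    max(abs(sweep(f$local_beta, 2, gb)))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
})

test_that("bandwidth selection is deterministic and tracks stationarity", {
  # stationary data: selected bandwidth at or near the upper bound
  set.seed(30)
  n <- 60
  coords <- cbind(runif(n, 0, 1e4), runif(n, 0, 1e4))
  d <- runif(n)
  y <- 1 + 3 * d + rnorm(n, 0, 0.2)
  des <- gwr_design(y, data.frame(d = d), coords)
  bw1 <- select_bandwidth(des, "bisquare", "adaptive")
  bw2 <- select_bandwidth(des, "bisquare", "adaptive")
  expect_identical(as.numeric(bw1), as.numeric(bw2))
  expect_gte(as.numeric(bw1), 0.8 * n)

  # strong step field: fixed-mode bandwidth well below the extent diagonal
  beta <- ifelse(coords[, 1] < 5e3, -6, 6)
  ys <- 1 + beta * d + rnorm(n, 0, 0.2)
  dess <- gwr_design(ys, data.frame(d = d), coords)
  bws <- select_bandwidth(dess, "gaussian", "fixed")
  expect_lt(as.numeric(bws), sqrt(2) * 1e4 / 4)
})

test_that("gwr localises a step coefficient field", {
  set.seed(55)
  n <- 120
  coords <- cbind(runif(n, 0, 1e4), runif(n, 0, 1e4))
  d <- runif(n, 0, 2)
  beta <- ifelse(coords[, 1] < 5e3, -4, 0)
  y <- 2 + beta * d
  des <- gwr_design(y, data.frame(d = d), coords)
  bw <- select_bandwidth(des, "bisquare", "adaptive")
  fit <- fit_gwr(des, "bisquare", bw, adaptive = TRUE)
  rec <- fit$local_beta[, "d"]
  off <- abs(coords[, 1] - 5e3) > 1e3
  expect_gte(mean(rec[off & beta < 0] < 0), 0.9)
  expect_gte(mean(abs(rec[off & beta == 0]) < 2), 0.9)
})

test_that("anova against the global model matches hand arithmetic", {
  fake <- structure(list(rss = 800, effective_params = 12, n = 192, p = 2),
                    class = "gwr_fit")
  out <- anova_vs_global(fake, global_rss = 1000)
  expect_equal(out$F, (200 / 10) / (800 / 180))  # 4.5
  expect_equal(out$p_value, stats::pf(4.5, 10, 180, lower.tail = FALSE))
  # identical fits: F = 0, p = 1
  same <- structure(list(rss = 1000, effective_params = 12, n = 192, p = 2),
                    class = "gwr_fit")
  out0 <- anova_vs_global(same, global_rss = 1000)
  expect_equal(out0$F, 0)
  expect_equal(out0$p_value, 1)
  # undefined when effective params do not exceed global params
  degen <- structure(list(rss = 800, effective_params = 2, n = 192, p = 2),
                     class = "gwr_fit")
  expect_true(is.na(anova_vs_global(degen, 1000)$F))
})

test_that("binomial gwr recovers a global logistic fit at huge bandwidth", {
  set.seed(77)
  n <- 80
  coords <- cbind(runif(n, 0, 1e4), runif(n, 0, 1e4))
  d <- runif(n, -2, 2)
  p <- 1 / (1 + exp(-(0.5 + 1.5 * d)))
  y <- rbinom(n, 1, p)
  des <- gwr_design(y, data.frame(d = d), coords, family = "binomial")
  fit <- fit_gwr(des, "gaussian", bandwidth = 1e6 * max(dist(coords)),
                 adaptive = FALSE)
  glob <- stats::glm(y ~ d, family = stats::binomial())
  expect_equal(unname(fit$local_beta[1, ]), unname(stats::coef(glob)),
               tolerance = 1e-5)
  expect_true(all(fit$converged))
  expect_true(fit$pseudo_r2 > 0)
})

test_that("monte carlo p-values separate stationary from step fields", {
  # stationary data at a huge bandwidth: local betas identical, p near 1
  set.seed(88)
  n <- 40
  coords <- cbind(runif(n, 0, 1e4), runif(n, 0, 1e4))
  d <- runif(n)
  y <- 1 + 2 * d + rnorm(n, 0, 0.5)
  des <- gwr_design(y, data.frame(d = d), coords)
  mc <- monte_carlo_nonstationarity(des, "gaussian",
                                    bandwidth = 1e4 * max(dist(coords)),
                                    adaptive = FALSE, n_permutations = 19,
                                    seed = 1)
  expect_gte(mc$p_value[["d"]], 0.9)
  expect_true(all(mc$p_value > 0 & mc$p_value <= 1))

  # noiseless step field: p at the permutation floor
  set.seed(89)
  n <- 100
  coords <- cbind(runif(n, 0, 1e4), runif(n, 0, 1e4))
  d <- runif(n, 0, 2)
  beta <- ifelse(coords[, 1] < 5e3, -4, 0)
  ys <- 1 + beta * d
  dess <- gwr_design(ys, data.frame(d = d), coords)
  mcs <- monte_carlo_nonstationarity(dess, "bisquare", bandwidth = 30,
                                     adaptive = TRUE, n_permutations = 99,
                                     seed = 2)
  expect_lte(mcs$p_value[["d"]], 0.05)
  # reproducible for a fixed seed
  mcs2 <- monte_carlo_nonstationarity(dess, "bisquare", bandwidth = 30,
                                      adaptive = TRUE, n_permutations = 99,
                                      seed = 2)
  expect_identical(mcs$p_value, mcs2$p_value)
  # covariate summary carries ranges and p-values
  fit <- fit_gwr(dess, "bisquare", 30, adaptive = TRUE)
  summ <- gwr_covariate_summary(fit, mcs)
  expect_equal(summ$covariate, c("(Intercept)", "d"))
  expect_true(all(summ$estimate_low <= summ$estimate_high))
  expect_equal(summ$monte_carlo_p, unname(mcs$p_value))
})
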