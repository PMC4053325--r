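yrs <- 2002:2011

test_that("span selection reproduces an independent AICc grid search", {
  set.seed(3)
  noisy <- 20 + 5 * sin(2 * pi * yrs / 6) + rnorm(10, 0, 2)
  spans <- seq(0.3, 1, by = 0.1)
  sel <- select_lowess_span(yrs, noisy, spans)
  oracle <- vapply(spans, function(s) oracle_span_aicc(yrs, noisy, s),
                   numeric(1))
  expect_equal(as.numeric(sel), spans[which.min(oracle)])
  expect_lt(as.numeric(sel), max(spans))  # periodic data wants a local fit
  expect_equal(unname(attr(sel, "aicc")), oracle, tolerance = 1e-8)
})

test_that("span selection handles degenerate series and short input", {
  # constant series: every span is perfect, ties break to the smallest
  sel <- select_lowess_span(yrs, rep(7, 10))
  sm <- lowess_logit_smooth(yrs, rep(7, 10), sel)
  expect_equal(unname(sm), rep(7, 10))
  expect_warning(select_lowess_span(2008:2011, c(1, 2, 3, 4)),
                 "fewer than 5")
})

test_that("smoother reproduces linear data and respects count bounds", {
  for (span in c(0.3, 0.6, 1)) {
    line <- 25 - 1.5 * (yrs - 2002)
    sm <- lowess_logit_smooth(yrs, line, span)
    expect_equal(unname(sm), line, tolerance = 1e-6)
  }
  # smooth positive input stays within 5% under the selected span
  gentle <- 30 + 2 * sin(2 * pi * yrs / 20)
  span <- suppressWarnings(select_lowess_span(yrs, gentle))
  sm <- lowess_logit_smooth(yrs, gentle, span)
  expect_true(all(abs(sm - gentle) / gentle < 0.05))
  # pure alternation is damped strictly inside the band, on both scales
  alt <- rep(c(10, 14), 5)
  for (scale in c("count", "logit")) {
    sm <- lowess_logit_smooth(yrs, alt, 0.5, scale = scale)
    expect_true(all(sm > 10 & sm < 14))
  }
  # all-zero series maps to zeros
  expect_equal(unname(lowess_logit_smooth(yrs, rep(0, 10), 0.5)),
               rep(0, 10))
  # output never leaves [0, cmax + 1)
  set.seed(8)
  for (r in 1:10) {
    cnt <- rpois(10, 6)
    for (scale in c("count", "logit")) {
      sm <- lowess_logit_smooth(yrs, cnt, runif(1, 0.3, 1), scale = scale)
      expect_true(all(sm >= 0 & sm < max(cnt) + 1))
    }
  }
})

test_that("smoother predicts unsurveyed years inside the window", {
  obs_yrs <- c(2002, 2003, 2005, 2007, 2008, 2010, 2011)
  cnt <- 20 - (obs_yrs - 2002)
  sm <- lowess_logit_smooth(obs_yrs, cnt, 0.7, eval_years = yrs)
  expect_length(sm, 10)
  expect_equal(unname(sm), 20 - (yrs - 2002), tolerance = 1e-6)
})

test_that("window trends equal the closed-form OLS slope", {
  adj <- stats::setNames(c(10, 8, 6, 4, 2), 2007:2011)
  expect_equal(window_trend(adj, 5, 2011)$value, -2)
  expect_equal(window_trend(stats::setNames(rep(4, 10), yrs), 10,
                            2011)$value, 0)
  set.seed(5)
  v <- rnorm(10)
  adj <- stats::setNames(v, yrs)
  for (w in c(3, 5, 10)) {
    win <- yrs[(10 - w + 1):10]
    vv <- v[(10 - w + 1):10]
    closed <- sum((win - mean(win)) * (vv - mean(vv))) /
      sum((win - mean(win))^2)
    expect_equal(window_trend(adj, w, 2011)$value, closed)
  }
  # reversing the series negates the slope
  rev_adj <- stats::setNames(rev(v), yrs)
  expect_equal(window_trend(rev_adj, 10, 2011)$value,
               -window_trend(adj, 10, 2011)$value)
  expect_error(window_trend(adj[1:5], 10, 2011), "missing")
})

test_that("full smoothing + trend stack is unbiased on linear series", {
  for (s in c(-2, -0.5, 0.3, 1.7)) {
    cnt <- 30 + s * (yrs - 2002)
    span <- suppressWarnings(select_lowess_span(yrs, cnt))
    adj <- lowess_logit_smooth(yrs, cnt, span, eval_years = yrs)
    for (w in c(3, 5, 10)) {
      expect_equal(window_trend(adj, w, 2011)$value, s, tolerance = 1e-6)
    }
  }
})

test_that("binary response thresholds at zero with a documented tie-break", {
  tr <- function(v) structure(list(lek_id = "A", kind = "trend5", value = v,
                                   window_start_year = 2007,
                                   window_end_year = 2011),
                              class = "trend_response")
  expect_equal(binary_response(tr(-1.89))$value, 0)
  expect_equal(binary_response(tr(3.2))$value, 1)
  expect_equal(binary_response(tr(0))$value, 0)
})

test_that("per-lek response table carries all five response kinds", {
  ext <- c(0, 2e4, 0, 2e4)
  leks <- generate_leks(6, ext, seed = 21)
  truth <- simulation_truth(baseline = 25, amplitude = 3, period = 6,
                            noise = "poisson")
  counts <- generate_counts(leks, pad_table(character(0), numeric(0),
                                            numeric(0)),
                            truth, 2002:2011, seed = 22)
  cfg <- analysis_config()
  resp <- lek_trend_responses(counts, cfg, 2011)
  expect_setequal(names(resp), c("lek_id", "x", "y", "span", "trend3",
                                 "trend5", "trend10",
                                 "adjusted_final_count", "binary"))
  expect_true(all(resp$binary %in% c(0, 1)))
  expect_equal(resp$binary, as.numeric(resp$trend5 > 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trend_responses(resp, path)
  long <- utils::read.csv(path)
  expect_equal(nrow(long), 6 * 5)
  expect_setequal(unique(long$kind), c("trend3", "trend5", "trend10",
                                       "adjusted_final_count", "binary"))
})
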