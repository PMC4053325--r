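mk_fit <- function(t_vals, beta = t_vals, n = length(t_vals) + 50,
                   eff = 5) {
  m <- cbind("(Intercept)" = 0, d = beta)
  tm <- cbind("(Intercept)" = 0, d = t_vals)
  structure(list(local_beta = m, local_se = m * 0 + 1, local_t = tm,
                 coords = cbind(x = seq_along(t_vals) * 1000, y = 0),
                 n = n, p = 2, effective_params = eff),
            class = "gwr_fit")
}

test_that("significance selection follows the t threshold and alpha", {
  expect_equal(nrow(significant_leks(mk_fit(rep(0, 6)), "d", 0.05)), 0)
  # |t| = 2.5 at df = 100 exceeds the 1.984 critical value
  fit <- mk_fit(c(2.5, 1.0, -2.5), n = 100 + 5, eff = 5)
  sig <- significant_leks(fit, "d", 0.05)
  expect_equal(sig$lek, c(1, 3))
  expect_equal(round(stats::qt(0.975, 100), 3), 1.984)
  # vanishing alpha empties the selection
  expect_equal(nrow(significant_leks(fit, "d", 1e-12)), 0)
  # monotone in alpha
  set.seed(14)
  fitr <- mk_fit(rnorm(40, 0, 2))
  sel <- lapply(c(0.01, 0.05, 0.2), function(a)
    significant_leks(fitr, "d", a)$lek)
  expect_true(all(sel[[1]] %in% sel[[2]]) && all(sel[[2]] %in% sel[[3]]))
  # BH screening is never more liberal than the raw per-lek test
  expect_true(all(significant_leks(fitr, "d", 0.05, adjust = "BH")$lek %in%
                    significant_leks(fitr, "d", 0.05)$lek))
})

test_that("idw interpolation is exact at samples and convex elsewhere", {
  grid <- list(origin = c(0, 0), cell_size = 100, nrows = 10, ncols = 10)
  # single point: constant surface (to rounding)
  s1 <- idw_interpolate(cbind(450, 450), -1.89, grid)
  expect_equal(s1$values, matrix(-1.89, 10, 10))
  expect_identical(s1$values[6, 5], -1.89)  # coincident cell is exact
  # cell centred on a sample takes its value exactly
  pts <- rbind(c(150, 150), c(850, 650))
  s2 <- idw_interpolate(pts, c(-1.89, 4), grid)
  expect_equal(s2$values[9, 2], -1.89)  # row 9 from top = y 150
  # equidistant cell averages the two samples
  ptsE <- rbind(c(100, 450), c(800, 450))
  s3 <- idw_interpolate(ptsE, c(2, 4), grid)
  expect_equal(s3$values[6, 5], 3)  # centre (450, 450) is equidistant
  # convex-combination bound on random instances
  set.seed(4)
  for (r in 1:5) {
    pp <- cbind(runif(7, 0, 1000), runif(7, 0, 1000))
    vv <- rnorm(7)
    s <- idw_interpolate(pp, vv, grid, power = runif(1, 0.5, 3))
    expect_true(all(s$values >= min(vv) - 1e-12 &
                      s$values <= max(vv) + 1e-12))
  }
  # empty point set: all no-data
  s0 <- idw_interpolate(matrix(numeric(0), ncol = 2), numeric(0), grid)
  expect_true(all(is.na(s0$values)))
})

test_that("esri ascii grids round-trip through write and read", {
  vals <- matrix(c(1.5, NA, -2, 0.25, 7, 3), nrow = 2, byrow = TRUE)
  surf <- lek_surface(c(1000, 2000), 250, vals)
  path <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(surf, path)
  expect_match(readLines(path)[6], "NODATA_value -9999")
  back <- read_esri_ascii(path)
  expect_equal(back$values, vals)
  expect_equal(back$origin, c(1000, 2000))
  expect_equal(back$cell_size, 250)
})

test_that("region summaries are exact means and survive reordering", {
  subset <- data.frame(lek_id = "A", beta = -1.89)
  dens <- data.frame(lek_id = "A", density = 0.14)
  rs <- region_summary(subset, dens)
  expect_equal(rs, list(mean_density = 0.14, mean_rate = -1.89, n = 1L))

  sub2 <- data.frame(lek_id = c("A", "B"), beta = c(-1, -3))
  den2 <- data.frame(lek_id = c("B", "A"), density = c(0.3, 0.1))
  rs2 <- region_summary(sub2, den2)
  expect_equal(rs2$mean_rate, -2)
  expect_equal(rs2$mean_density, 0.2)
  # permutation invariance + one-pass oracle
  set.seed(2)
  sub3 <- data.frame(lek_id = sprintf("L%d", 1:12), beta = rnorm(12))
  den3 <- data.frame(lek_id = sample(sub3$lek_id), density = runif(12))
  rs3 <- region_summary(sub3, den3)
  rs3p <- region_summary(sub3[sample(12), ], den3)
  expect_equal(rs3$mean_rate, mean(sub3$beta))
  expect_equal(rs3$mean_density, mean(den3$density))
  expect_equal(rs3p$mean_rate, rs3$mean_rate)
  # empty subset: explicit empty summary, not zeros
  expect_equal(region_summary(sub3[0, ], den3)$n, 0L)
  expect_true(is.na(region_summary(sub3[0, ], den3)$mean_rate))
})

test_that("opposing-response pairing is tolerance-bounded and one-to-one", {
  resp <- data.frame(lek_id = c("up1", "dn1"), trend = c(3.2, -5.7))
  dens <- data.frame(lek_id = c("up1", "dn1"), density = c(0.5, 0.5))
  pairs <- opposing_response_pairs(resp, dens, tolerance = 0.05)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$trend_up, 3.2)
  expect_equal(pairs$trend_down, -5.7)

  # all declining: nothing to pair
  respd <- data.frame(lek_id = c("a", "b"), trend = c(-1, -2))
  expect_equal(nrow(opposing_response_pairs(
    respd, data.frame(lek_id = c("a", "b"), density = c(1, 1)))), 0)

  # zero tolerance with distinct densities: no pair
  densd <- data.frame(lek_id = c("up1", "dn1"), density = c(0.5, 0.51))
  expect_equal(nrow(opposing_response_pairs(resp, densd, tolerance = 0)), 0)

  # each decreasing lek is used at most once
  resp3 <- data.frame(lek_id = c("u1", "u2", "d1"),
                      trend = c(1, 2, -1))
  dens3 <- data.frame(lek_id = c("u1", "u2", "d1"),
                      density = c(0.5, 0.5, 0.5))
  pairs3 <- opposing_response_pairs(resp3, dens3)
  expect_equal(nrow(pairs3), 1)
})

test_that("grid specs cover their points with padding", {
  pts <- cbind(c(0, 9500), c(0, 4500))
  gs <- surface_grid_spec(pts, cell_size = 1000, pad_m = 500)
  expect_equal(gs$origin, c(-500, -500))
  expect_equal(gs$ncols, 11)
  expect_equal(gs$nrows, 6)
})
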