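# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: densities by naive all-pairs loops, local fits
# via stats::lm, smoother rows by applying an lm-based local regression to
# unit vectors.

# naive O(n*m) roving-window density
oracle_density <- function(pads, centers, radius_km, year) {
  act <- pads[!is.na(pads$start_year) & pads$start_year <= year &
                (is.na(pads$end_year) | pads$end_year >= year) &
                pads$class != "AP", ]
  out <- numeric(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    k <- 0
    for (j in seq_len(nrow(act))) {
      d <- sqrt((act$x[j] - centers$x[i])^2 + (act$y[j] - centers$y[i])^2)
      if (d <= radius_km * 1000) k <- k + 1
    }
    out[i] <- k / (pi * radius_km^2)
  }
  out
}

# brute-force weighted normal-equation solve at one focal point, via lm
oracle_wls <- function(X, y, w) {
  keep <- w > 0
  fit <- stats::lm(y[keep] ~ X[keep, -1, drop = FALSE], weights = w[keep])
  unname(stats::coef(fit))
}

# local-linear smoothed value at x0 via stats::lm
oracle_smooth_at <- function(x, y, span, x0) {
  n <- length(x)
  q <- max(3L, min(n, as.integer(ceiling(span * n))))
  d <- abs(x - x0)
  h <- sort(d)[q] * 1.05
  w <- (1 - pmin(d / h, 1)^3)^3
  fit <- stats::lm(y ~ I(x - x0), weights = w)
  unname(stats::coef(fit)[1])
}

# AICc of one span, built by smoothing the unit vectors (row-by-row
# reconstruction of the smoother matrix through the lm oracle)
oracle_span_aicc <- function(x, y, span) {
  n <- length(x)
  S <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    S[, j] <- vapply(x, function(x0) oracle_smooth_at(x, e, span, x0),
                     numeric(1))
  }
  k <- sum(diag(S))
  rss <- sum((y - drop(S %*% y))^2)
  if (n - k - 1 <= 0) return(Inf)
  n * log(max(rss, 1e-300) / n) + 2 * k * n / (n - k - 1)
}

# small random GWR design
random_design <- function(n, p = 2, seed = 1, extent = 1e4) {
  set.seed(seed)
  coords <- cbind(runif(n, 0, extent), runif(n, 0, extent))
  X <- as.data.frame(matrix(runif(n * (p - 1)), n))
  names(X) <- paste0("v", seq_len(p - 1))
  y <- rnorm(n)
  gwr_design(y, X, coords)
}
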