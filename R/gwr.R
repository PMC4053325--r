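#' Assemble a GWR design
#'
#' Binds one response vector, the selected density covariates and the lek
#' coordinates into an aligned design for geographically weighted
#' regression.  An intercept column is added in front of the covariates.
#'
#' @param y numeric response vector (one trend-response kind across leks;
#'   0/1 for the binomial family).
#' @param covariates data.frame or matrix of covariate columns (no
#'   intercept), rows aligned with `y`.
#' @param coords two-column matrix or data.frame of planar coordinates (m).
#' @param family `"gaussian"` or `"binomial"`.
#' @return An object of class `gwr_design`.
#' @export
gwr_design <- function(y, covariates, coords,
                       family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  X <- cbind("(Intercept)" = 1, as.matrix(covariates))
  coords <- as.matrix(as.data.frame(coords)[, 1:2])
  stopifnot(length(y) == nrow(X), nrow(coords) == nrow(X),
            all(is.finite(X)), all(is.finite(coords)), all(is.finite(y)))
  if (qr(X)$rank < ncol(X)) {
    stop("covariate matrix is globally rank deficient", call. = FALSE)
  }
  if (family == "binomial" && !all(y %in% c(0, 1))) {
    stop("binomial family requires a 0/1 response", call. = FALSE)
  }
  structure(list(y = as.numeric(y), X = X, coords = coords, family = family),
            class = "gwr_design")
}

#' Spatial kernel weights around a focal location
#'
#' Distance-decay weights for the local fit at one lek.  Gaussian:
#' \eqn{w = \exp(-\frac{1}{2}(d/b)^2)}; bisquare:
#' \eqn{w = (1-(d/b)^2)^2} for \eqn{d < b}, else 0.  The self-weight at
#' \eqn{d = 0} is 1.  In adaptive mode the bandwidth is a neighbour count
#' \eqn{k} and the kernel scale at each focal point is the distance to its
#' k-th nearest neighbour (the focal point itself included), so the kernel
#' adapts to local lek density.
#'
#' @param coords two-column coordinate matrix (m).
#' @param focal_index row index of the focal location.
#' @param bandwidth kernel scale in metres (fixed) or neighbour count
#'   (adaptive).
#' @param kernel `"bisquare"` or `"gaussian"`.
#' @param adaptive logical; interpret `bandwidth` as a neighbour count.
#' @return Numeric weight vector, one element per row of `coords`.
#' @export
kernel_weights <- function(coords, focal_index, bandwidth,
                           kernel = c("bisquare", "gaussian"),
                           adaptive = FALSE) {
  kernel <- match.arg(kernel)
  coords <- as.matrix(coords)
  d <- sqrt((coords[, 1] - coords[focal_index, 1])^2 +
              (coords[, 2] - coords[focal_index, 2])^2)
  kernel_weights_dist(d, bandwidth, kernel, adaptive)
}

kernel_weights_dist <- function(d, bandwidth, kernel, adaptive) {
  b <- if (adaptive) {
    k <- max(2L, min(length(d), as.integer(round(bandwidth))))
    max(sort(d, partial = k)[k], .Machine$double.eps)
  } else bandwidth
  stopifnot(b > 0)
  if (kernel == "gaussian") {
    exp(-0.5 * (d / b)^2)
  } else {
    w <- (1 - (d / b)^2)^2
    w[d >= b] <- 0
    w
  }
}

#' Weighted least-squares fit at one focal lek
#'
#' Solves the kernel-weighted normal equations
#' \eqn{\hat\beta = (X'WX)^{-1}X'Wy} and returns local standard errors from
#' the weighted covariance \eqn{\sigma^2 (X'WX)^{-1}X'W^2X(X'WX)^{-1}}.
#' For the gaussian family \eqn{\sigma^2} should be the model-level error
#' variance of the full GWR fit (passed as `sigma2`); if absent, a local
#' estimate from the weighted residuals is used.  The binomial family fits
#' a kernel-weighted logistic regression by iteratively reweighted least
#' squares.
#'
#' @param X design matrix (intercept included).
#' @param y response vector.
#' @param weights kernel weights (see [kernel_weights()]).
#' @param family `"gaussian"` or `"binomial"`.
#' @param sigma2 optional model-level error variance for the SEs.
#' @return list with `beta`, `se`, and (binomial) `converged`; `NULL` if
#'   the weighted design is rank deficient.
#' @export
fit_local <- function(X, y, weights, family = "gaussian", sigma2 = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (family == "binomial") {
    return(fit_local_binomial(X, y, weights))
  }
  A <- crossprod(X, weights * X)
  ok <- tryCatch({
    Ainv <- solve(A)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) return(NULL)
  M <- Ainv %*% t(weights * X)            # p x n: beta = M y
  beta <- drop(M %*% y)
  if (is.null(sigma2)) {
    e <- y - drop(X %*% beta)
    df <- sum(weights) - p
    sigma2 <- if (df > 0) sum(weights * e^2) / df else NA_real_
  }
  se <- sqrt(pmax(sigma2 * rowSums(M * M), 0))
  list(beta = stats::setNames(beta, colnames(X)),
       se = stats::setNames(se, colnames(X)), M = M)
}

fit_local_binomial <- function(X, y, weights, max_iter = 25, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  converged <- FALSE
  W_work <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W_work <- weights * mu * (1 - mu)
    A <- crossprod(X, W_work * X)
    ok <- tryCatch({
      delta <- solve(A, crossprod(X, weights * (y - mu)))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) return(NULL)
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  A <- crossprod(X, W_work * X)
  se <- tryCatch(sqrt(pmax(diag(solve(A)), 0)), error = function(e) rep(NA_real_, p))
  list(beta = stats::setNames(beta, colnames(X)),
       se = stats::setNames(se, colnames(X)),
       work_weights = W_work, converged = converged)
}

#' Fit a geographically weighted regression
#'
#' Runs [fit_local()] at every lek with kernel weights centred there,
#' assembling local coefficients, standard errors and t-values, the hat
#' matrix traces, effective parameters \eqn{2\mathrm{tr}(S) -
#' \mathrm{tr}(S'S)}, the corrected AIC
#' \eqn{AICc = n\log(RSS/n) + n\log(2\pi) +
#'   n\,(n + \mathrm{tr}(S)) / (n - 2 - \mathrm{tr}(S))}
#' and a pseudo-R^2 (1 - RSS/TSS for gaussian; a deviance ratio for
#' binomial).  Pseudo-R^2 values are not bounded by 0-1 and are not
#' comparable across responses with different magnitudes or variance
#' structure; the fit records that caveat in its `notes` field.
#'
#' Rank-deficient local fits are flagged (`flagged`), excluded from the
#' coefficient maps (rows of `NA`), and the run continues.
#'
#' @param design a [gwr_design()].
#' @param kernel `"bisquare"` or `"gaussian"`.
#' @param bandwidth metres (fixed) or neighbour count (adaptive).
#' @param adaptive logical.
#' @return An object of class `gwr_fit`.
#' @export
fit_gwr <- function(design, kernel = c("bisquare", "gaussian"), bandwidth,
                    adaptive = TRUE) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(design, "gwr_design"))
  X <- design$X; y <- design$y
  n <- nrow(X); p <- ncol(X)
  D <- as.matrix(stats::dist(design$coords))
  beta <- se <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(X)))
  Mdiag <- matrix(NA_real_, n, p)   # diag of M M' per lek (gaussian SEs)
  S <- matrix(0, n, n)
  fitted <- rep(NA_real_, n)
  flagged <- logical(n)
  converged <- rep(TRUE, n)

  for (i in seq_len(n)) {
    w <- kernel_weights_dist(D[i, ], bandwidth, kernel, adaptive)
    loc <- fit_local(X, y, w, family = design$family, sigma2 = NA)
    if (is.null(loc)) {
      flagged[i] <- TRUE
      next
    }
    beta[i, ] <- loc$beta
    if (design$family == "gaussian") {
      Mdiag[i, ] <- rowSums(loc$M * loc$M)
      S[i, ] <- X[i, ] %*% loc$M
      fitted[i] <- drop(S[i, ] %*% y)
    } else {
      se[i, ] <- loc$se
      converged[i] <- loc$converged
      fitted[i] <- 1 / (1 + exp(-drop(X[i, ] %*% loc$beta)))
      # working-response hat row for effective-parameter accounting
      A <- crossprod(X, loc$work_weights * X)
      S[i, ] <- tryCatch(
        drop((X[i, ] %*% solve(A)) %*% t(loc$work_weights * X)),
        error = function(e) rep(0, n))
    }
  }

  ok <- !flagged
  resid <- y - fitted
  tr_s <- sum(diag(S))
  tr_sts <- sum(S * S)
  eff_p <- 2 * tr_s - tr_sts
  if (design$family == "gaussian") {
    rss <- sum(resid[ok]^2)
    tss <- sum((y[ok] - mean(y[ok]))^2)
    sigma2 <- rss / max(n - eff_p, 1e-8)
    se[ok, ] <- sqrt(pmax(sigma2 * Mdiag[ok, , drop = FALSE], 0))
    aicc <- if (n - 2 - tr_s > 0) {
      n * log(rss / n) + n * log(2 * pi) + n * (n + tr_s) / (n - 2 - tr_s)
    } else Inf
    pseudo_r2 <- 1 - rss / tss
    deviance <- NA_real_
  } else {
    mu <- pmin(pmax(fitted, 1e-12), 1 - 1e-12)
    deviance <- -2 * sum(y[ok] * log(mu[ok]) + (1 - y[ok]) * log(1 - mu[ok]))
    p0 <- mean(y[ok])
    null_dev <- -2 * sum(y[ok] * log(p0) + (1 - y[ok]) * log(1 - p0))
    rss <- sum(resid[ok]^2)
    sigma2 <- NA_real_
    aicc <- if (n - tr_s - 1 > 0) {
      deviance + 2 * tr_s + 2 * tr_s * (tr_s + 1) / (n - tr_s - 1)
    } else Inf
    pseudo_r2 <- 1 - deviance / null_dev
  }
  tvals <- beta / se
  tvals[se == 0] <- NA_real_

  structure(list(
    bandwidth = bandwidth, kernel = kernel, adaptive = adaptive,
    family = design$family,
    local_beta = beta, local_se = se, local_t = tvals,
    hat_trace = tr_s, hat_trace_sts = tr_sts, effective_params = eff_p,
    residuals = resid, fitted = fitted, rss = rss, sigma2 = sigma2,
    deviance = deviance, aicc = aicc, pseudo_r2 = pseudo_r2,
    flagged = flagged, converged = converged,
    coords = design$coords, n = n, p = p,
    notes = paste("pseudo-R^2 values are not bounded 0-1 and are not",
                  "comparable across responses with differing magnitude",
                  "or variance structure")
  ), class = "gwr_fit")
}

#' @export
print.gwr_fit <- function(x, ...) {
  cat("<gwr_fit>", x$family, "family,", x$kernel, "kernel,",
      if (x$adaptive) "adaptive" else "fixed", "bandwidth =",
      format(x$bandwidth), "\n")
  cat("  n =", x$n, " covariates =", x$p,
      " effective params =", round(x$effective_params, 1), "\n")
  cat("  AICc =", round(x$aicc, 2), " pseudo-R2 =", round(x$pseudo_r2, 4),
      "(not bounded 0-1)\n")
  if (any(x$flagged)) cat("  flagged (rank-deficient) leks:",
                          sum(x$flagged), "\n")
  invisible(x)
}

# Lean evaluator used by bandwidth selection: local betas, fitted values
# and tr(S) only (no full hat matrix, no SEs).
gwr_score <- function(X, y, D, bandwidth, kernel, adaptive, family) {
  n <- nrow(X)
  fitted <- rep(NA_real_, n)
  tr_s <- 0
  for (i in seq_len(n)) {
    w <- kernel_weights_dist(D[i, ], bandwidth, kernel, adaptive)
    if (family == "binomial") {
      loc <- fit_local_binomial(X, y, w)
      if (is.null(loc)) return(Inf)
      fitted[i] <- 1 / (1 + exp(-drop(X[i, ] %*% loc$beta)))
      A <- crossprod(X, loc$work_weights * X)
      sii <- tryCatch(
        loc$work_weights[i] * drop(X[i, ] %*% solve(A, X[i, ])),
        error = function(e) return(0))
      tr_s <- tr_s + sii
    } else {
      A <- crossprod(X, w * X)
      beta <- tryCatch(solve(A, crossprod(X, w * y)),
                       error = function(e) NULL)
      if (is.null(beta)) return(Inf)
      fitted[i] <- drop(X[i, ] %*% beta)
      tr_s <- tr_s + w[i] * drop(X[i, ] %*% solve(A, X[i, ]))
    }
  }
  if (family == "gaussian") {
    rss <- sum((y - fitted)^2)
    if (n - 2 - tr_s <= 0) return(Inf)
    n * log(rss / n) + n * log(2 * pi) + n * (n + tr_s) / (n - 2 - tr_s)
  } else {
    mu <- pmin(pmax(fitted, 1e-12), 1 - 1e-12)
    dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (n - tr_s - 1 <= 0) return(Inf)
    dev + 2 * tr_s + 2 * tr_s * (tr_s + 1) / (n - tr_s - 1)
  }
}

#' Select a GWR bandwidth by AICc
#'
#' Golden-section search for the bandwidth minimising the GWR corrected
#' AIC.  The search interval is `[minimum positive pairwise distance,
#' extent diagonal]` in fixed mode and `[p + 2, n]` neighbours in adaptive
#' mode (evaluated at integer neighbour counts).  The AICc profile is
#' additionally scanned on a coarse grid; if the profile is not unimodal
#' and the grid finds a better optimum than the golden section, the grid
#' minimum is returned with a warning.  The procedure is deterministic.
#'
#' @param design a [gwr_design()] with `n >= 3 * (covariates + 1)` rows.
#' @param kernel `"bisquare"` or `"gaussian"`.
#' @param mode `"adaptive"` or `"fixed"`.
#' @return The selected bandwidth (neighbour count or metres), with the
#'   attained AICc as attribute `"aicc"`.
#' @export
select_bandwidth <- function(design, kernel = c("bisquare", "gaussian"),
                             mode = c("adaptive", "fixed")) {
  kernel <- match.arg(kernel)
  mode <- match.arg(mode)
  stopifnot(inherits(design, "gwr_design"))
  X <- design$X; y <- design$y
  n <- nrow(X); p <- ncol(X)
  if (n < 3 * p) stop("need at least 3 observations per covariate",
                      call. = FALSE)
  D <- as.matrix(stats::dist(design$coords))
  adaptive <- mode == "adaptive"
  if (adaptive) {
    lo <- p + 2; hi <- n
  } else {
    pos <- D[upper.tri(D)]
    lo <- min(pos[pos > 0])
    hi <- sqrt(diff(range(design$coords[, 1]))^2 +
                 diff(range(design$coords[, 2]))^2)
  }
  cache <- new.env(parent = emptyenv())
  f <- function(b) {
    b <- if (adaptive) round(b) else b
    key <- format(b, digits = 12)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- gwr_score(X, y, D, b, kernel, adaptive, design$family)
    cache[[key]] <- val
    val
  }
  # golden-section search
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  tol <- if (adaptive) 0.51 else (hi - lo) * 1e-3
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    }
  }
  golden <- if (f1 <= f2) c1 else c2
  if (adaptive) golden <- round(golden)
  golden_val <- f(golden)
  # include the endpoints and a coarse grid as a unimodality guard
  grid <- if (adaptive) {
    unique(pmin(pmax(round(seq(lo, hi, length.out = 10)), lo), hi))
  } else seq(lo, hi, length.out = 10)
  grid_vals <- vapply(grid, f, numeric(1))
  if (min(grid_vals) < golden_val - 1e-9) {
    warning("AICc bandwidth profile is not unimodal; using grid minimum")
    best <- grid[which.min(grid_vals)]
    # local refinement around the grid minimum
    if (adaptive) {
      cand <- unique(pmin(pmax(best + (-3:3), lo), hi))
      cv <- vapply(cand, f, numeric(1))
      best <- cand[which.min(cv)]
    }
    return(structure(best, aicc = f(best)))
  }
  structure(golden, aicc = golden_val)
}

#' F-test of GWR against the global model
#'
#' Approximate ANOVA comparing the GWR residual sum of squares against the
#' global (stationary-coefficient) least-squares fit of the same response:
#' \deqn{F = \frac{(RSS_{global} - RSS_{gwr}) / (ep - p)}
#'            {RSS_{gwr} / (n - ep)}}
#' with `ep` the GWR effective parameters; the p-value uses the F
#' distribution with those approximate degrees of freedom.
#'
#' @param fit a [fit_gwr()] result (gaussian family).
#' @param global_rss residual sum of squares of the global OLS fit.
#' @param n observations; defaults to the fit's.
#' @param p parameters of the global model; defaults to the fit's.
#' @return list with `F`, `p_value`, `df1`, `df2`; `F = NA` (test
#'   undefined) when the effective parameters do not exceed `p`.
#' @export
anova_vs_global <- function(fit, global_rss, n = fit$n, p = fit$p) {
  stopifnot(inherits(fit, "gwr_fit"))
  df1 <- fit$effective_params - p
  df2 <- n - fit$effective_params
  if (df1 <= 0 || df2 <= 0) {
    return(list(F = NA_real_, p_value = NA_real_, df1 = df1, df2 = df2,
                note = "test undefined: effective params <= global params"))
  }
  Fstat <- ((global_rss - fit$rss) / df1) / (fit$rss / df2)
  list(F = Fstat, p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}
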