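#' Analysis configuration
#'
#' Bundles the tunable parameters of the full pipeline with the defaults of
#' the Wyoming-style study design: pad densities at 0.5, 1, 2, 5 and 10 km
#' around leks, time lags of 1, 3, 5 and 10 years, and attendance trends over
#' the most recent 3, 5 and 10 years.
#'
#' @param radii_km positive reals; roving-window radii in kilometres.
#' @param lag_years non-negative integers; years between the pad-density
#'   snapshot and the start of the trend window it is hypothesised to affect.
#' @param trend_windows integers; lengths (years) of the trend regressions.
#' @param kernel GWR kernel, `"bisquare"` or `"gaussian"`.
#' @param bandwidth_mode `"adaptive"` (bandwidth is a neighbour count) or
#'   `"fixed"` (bandwidth in metres).
#' @param n_permutations positive integer; Monte Carlo permutations for the
#'   nonstationarity test.
#' @param alpha significance level in (0, 1) for local t-tests.
#' @param seed integer seed for all stochastic steps.
#' @param idw_power positive real; inverse-distance weighting exponent.
#' @param grid_cell_m positive real; interpolation grid cell size in metres.
#' @param lowess_spans candidate span grid for AICc selection, each in (0, 1].
#' @param lowess_scale scale on which the LOWESS smoother is fit: `"count"`
#'   (default; keeps windowed trend slopes exactly recoverable on linear
#'   series) or `"logit"` (empirical-logit transform before smoothing).
#'
#' @return An object of class `analysis_config` (a validated list).
#' @examples
#' cfg <- analysis_config(n_permutations = 99)
#' cfg$radii_km
#' @export
analysis_config <- function(radii_km = c(0.5, 1, 2, 5, 10),
                            lag_years = c(1L, 3L, 5L, 10L),
                            trend_windows = c(3L, 5L, 10L),
                            kernel = c("bisquare", "gaussian"),
                            bandwidth_mode = c("adaptive", "fixed"),
                            n_permutations = 99L,
                            alpha = 0.05,
                            seed = 1L,
                            idw_power = 2,
                            grid_cell_m = 1000,
                            lowess_spans = seq(0.3, 1, by = 0.1),
                            lowess_scale = c("count", "logit")) {
  kernel <- match.arg(kernel)
  bandwidth_mode <- match.arg(bandwidth_mode)
  lowess_scale <- match.arg(lowess_scale)
  stopifnot(
    "radii_km must be positive" = all(is.finite(radii_km) & radii_km > 0),
    "lag_years must be non-negative integers" =
      all(lag_years >= 0 & lag_years == round(lag_years)),
    "trend_windows must be integers >= 2" =
      all(trend_windows >= 2 & trend_windows == round(trend_windows)),
    "n_permutations must be a positive integer" =
      length(n_permutations) == 1 && n_permutations >= 1,
    "alpha must be in (0, 1)" = length(alpha) == 1 && alpha > 0 && alpha < 1,
    "idw_power must be positive" = length(idw_power) == 1 && idw_power > 0,
    "grid_cell_m must be positive" =
      length(grid_cell_m) == 1 && grid_cell_m > 0,
    "lowess_spans must lie in (0, 1]" =
      all(lowess_spans > 0 & lowess_spans <= 1)
  )
  structure(
    list(
      radii_km = as.numeric(radii_km),
      lag_years = as.integer(lag_years),
      trend_windows = as.integer(trend_windows),
      kernel = kernel,
      bandwidth_mode = bandwidth_mode,
      n_permutations = as.integer(n_permutations),
      alpha = alpha,
      seed = as.integer(seed),
      idw_power = idw_power,
      grid_cell_m = grid_cell_m,
      lowess_spans = sort(as.numeric(lowess_spans)),
      lowess_scale = lowess_scale
    ),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat("  radii_km:      ", paste(x$radii_km, collapse = ", "), "\n")
  cat("  lag_years:     ", paste(x$lag_years, collapse = ", "), "\n")
  cat("  trend_windows: ", paste(x$trend_windows, collapse = ", "), "\n")
  cat("  kernel:        ", x$kernel, "(", x$bandwidth_mode, ")\n")
  cat("  permutations:  ", x$n_permutations, " alpha: ", x$alpha, "\n")
  invisible(x)
}
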