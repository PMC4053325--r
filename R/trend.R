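# Local-linear LOWESS smoother with an explicit smoother matrix.
#
# Row j of the returned matrix gives the weights that map the observed
# values to the smoothed value at eval_x[j]; the square matrix at
# eval_x = x is the smoother matrix S whose trace is the effective number
# of parameters used by the AICc span criterion.  Weights are tricube over
# the q = ceiling(span * n) nearest neighbours, with the neighbourhood
# scale inflated by 5% so the q-th neighbour retains a small positive
# weight and the weighted design stays full rank.  A local linear fit
# reproduces exactly linear data for every span, which keeps downstream
# windowed trend slopes unbiased on linear series.
lowess_matrix <- function(x, span, eval_x = x) {
  n <- length(x)
  stopifnot(n >= 2, span > 0, span <= 1)
  q <- max(3L, min(n, as.integer(ceiling(span * n))))
  L <- matrix(0, nrow = length(eval_x), ncol = n)
  for (j in seq_along(eval_x)) {
    d <- abs(x - eval_x[j])
    h <- sort(d, partial = q)[q] * 1.05
    if (h <= 0) h <- 1e-9
    w <- (1 - pmin(d / h, 1)^3)^3
    X <- cbind(1, x - eval_x[j])
    XtW <- t(X * w)
    A <- XtW %*% X
    # smoothed value at eval_x[j] is the local intercept
    L[j, ] <- solve(A, XtW)[1, ]
  }
  L
}

#' Select a LOWESS span by corrected AIC
#'
#' Grid-searches candidate spans, computing for each the smoother matrix
#' \eqn{S}, residual sum of squares and
#' \eqn{AICc = n\log(RSS/n) + 2kn/(n-k-1)} with \eqn{k = \mathrm{tr}(S)},
#' and returns the span minimising AICc.  Ties (including the degenerate
#' all-spans-perfect case of noiseless linear or constant series) break
#' toward the smallest span; spans whose effective parameters leave no
#' residual degrees of freedom (\eqn{n - k - 1 \le 0}) are treated as
#' unusable.
#'
#' @param years numeric survey years (>= 5 for a real selection; fewer
#'   falls back to the maximal candidate span with a warning).
#' @param counts observed counts, same length as `years`.
#' @param spans candidate grid in (0, 1].
#' @return The selected span, with attributes `aicc` (the candidate-wise
#'   values) and `k` (effective parameters of the winner).
#' @export
select_lowess_span <- function(years, counts, spans = seq(0.3, 1, by = 0.1)) {
  stopifnot(length(years) == length(counts), all(spans > 0 & spans <= 1))
  n <- length(years)
  spans <- sort(spans)
  if (n < 5) {
    warning("fewer than 5 observed years; falling back to maximal span")
    return(structure(max(spans), aicc = NULL, k = NA_real_))
  }
  aicc <- k_sel <- rep(NA_real_, length(spans))
  for (i in seq_along(spans)) {
    S <- lowess_matrix(years, spans[i])
    k <- sum(diag(S))
    rss <- sum((counts - drop(S %*% counts))^2)
    aicc[i] <- if (n - k - 1 <= 0) Inf
      else n * log(max(rss, 1e-300) / n) + 2 * k * n / (n - k - 1)
    k_sel[i] <- k
  }
  if (all(!is.finite(aicc) | aicc == Inf)) {
    warning("no candidate span has residual degrees of freedom; using max")
    best <- length(spans)
  } else {
    best <- which.min(aicc)  # first minimum = smallest span on ties
  }
  structure(spans[best], aicc = stats::setNames(aicc, spans), k = k_sel[best])
}

#' Periodicity-adjusted lek attendance by LOWESS smoothing
#'
#' Smooths a lek's yearly count series to remove multi-year periodicity and
#' evaluates the smooth at every requested year (including unsurveyed years,
#' by local-regression prediction), returning attendance values on the count
#' scale bounded to the lek's plausible range.
#'
#' Two fitting scales are supported.  The default `"count"` fits the local
#' linear smoother to the raw counts and bounds the result to
#' \eqn{[0, c_{max}+1)}; it is exactly unbiased for linear trends.  The
#' `"logit"` alternative maps counts to empirical proportions
#' \eqn{p = (c + 0.5)/(c_{max} + 1)} (the +0.5 offset keeps the logit finite
#' at 0 and at the maximum), smooths on the logit scale, and back-transforms,
#' which builds the range bound into the link at the cost of a small bias on
#' linear series.
#'
#' @param years surveyed years.
#' @param counts observed counts (>= 0), same length.
#' @param span LOWESS span in (0, 1].
#' @param eval_years years at which adjusted values are wanted (default the
#'   surveyed years).
#' @param scale `"count"` or `"logit"` (see Details).
#' @return Named numeric vector of adjusted attendance values, one per
#'   `eval_years`, always within \eqn{[0, c_{max}+1)}.
#' @export
lowess_logit_smooth <- function(years, counts, span, eval_years = years,
                                scale = c("count", "logit")) {
  scale <- match.arg(scale)
  stopifnot(length(years) == length(counts), all(counts >= 0))
  cmax <- max(counts)
  if (cmax == 0) {
    return(stats::setNames(rep(0, length(eval_years)), eval_years))
  }
  L <- lowess_matrix(years, span, eval_years)
  out <- if (scale == "count") {
    sm <- drop(L %*% counts)
    pmin(pmax(sm, 0), cmax)
  } else {
    p <- (counts + 0.5) / (cmax + 1)
    z <- drop(L %*% log(p / (1 - p)))
    pmax(1 / (1 + exp(-z)) * (cmax + 1) - 0.5, 0)
  }
  stats::setNames(out, eval_years)
}

#' Windowed linear trend of adjusted attendance
#'
#' Ordinary least-squares slope of the adjusted attendance values on year
#' over the `window` most recent years ending at `end_year` — the per-lek
#' response (males/lek/year) the spatial regressions model.
#'
#' @param adjusted named numeric vector of adjusted attendance values (names
#'   are years), covering the whole window.
#' @param window window length in years (3, 5 or 10 in the study design).
#' @param end_year final year of the window.
#' @param lek_id optional identifier carried into the result.
#' @return A `trend_response` list: `lek_id`, `kind` (e.g. `"trend5"`),
#'   `value` (slope), `window_start_year`, `window_end_year`.
#' @examples
#' adj <- setNames(c(10, 8, 6, 4, 2), 2007:2011)
#' window_trend(adj, 5, 2011)$value  # -2
#' @export
window_trend <- function(adjusted, window, end_year, lek_id = NA_character_) {
  yrs <- (end_year - window + 1):end_year
  miss <- setdiff(as.character(yrs), names(adjusted))
  if (length(miss)) {
    stop(sprintf("adjusted values missing for year(s) %s; smooth first",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  v <- as.numeric(adjusted[as.character(yrs)])
  slope <- sum((yrs - mean(yrs)) * (v - mean(v))) / sum((yrs - mean(yrs))^2)
  structure(list(lek_id = lek_id, kind = paste0("trend", window),
                 value = slope, window_start_year = yrs[1],
                 window_end_year = end_year),
            class = "trend_response")
}

#' Binary increasing/decreasing response
#'
#' Collapses a trend slope to the binomial response used for comparison
#' with logistic analyses: 1 when the lek is increasing (slope strictly
#' positive), 0 otherwise (an exactly flat slope counts as not increasing).
#'
#' @param trend a `trend_response` from [window_trend()].
#' @return A `trend_response` with `kind = "binary"` and value in {0, 1}.
#' @export
binary_response <- function(trend) {
  stopifnot(inherits(trend, "trend_response"))
  structure(list(lek_id = trend$lek_id, kind = "binary",
                 value = as.numeric(trend$value > 0),
                 window_start_year = trend$window_start_year,
                 window_end_year = trend$window_end_year),
            class = "trend_response")
}

#' All trend responses for every lek
#'
#' Runs the detrending stack per lek over the 10-year window ending at
#' `final_year`: AICc span selection, LOWESS adjustment evaluated at all 10
#' years, windowed trend slopes for each window length, the adjusted
#' final-year count, and the binary increasing/decreasing flag (derived from
#' the 5-year trend, the most supported response period).
#'
#' @param leks a [lek_table] (typically already passed through
#'   [filter_eligible_leks()]).
#' @param config an [analysis_config] (`trend_windows`, `lowess_spans`,
#'   `lowess_scale`).
#' @param final_year last year of the window.
#' @return data.frame with one row per lek: `lek_id`, `x`, `y`, `span`, one
#'   `trend<w>` column per window, `adjusted_final_count`, and `binary`.
#' @export
lek_trend_responses <- function(leks, config, final_year) {
  stopifnot(inherits(leks, "lek_table"), inherits(config, "analysis_config"))
  final_year <- as.integer(final_year)
  win_years <- (final_year - 9L):final_year
  ids <- unique(leks$lek_id)
  rows <- lapply(ids, function(id) {
    d <- leks[leks$lek_id == id & leks$year %in% win_years, ]
    span <- suppressWarnings(
      select_lowess_span(d$year, d$males, config$lowess_spans))
    adj <- lowess_logit_smooth(d$year, d$males, span,
                               eval_years = win_years,
                               scale = config$lowess_scale)
    out <- data.frame(lek_id = id, x = d$x[1], y = d$y[1],
                      span = as.numeric(span), stringsAsFactors = FALSE)
    tr5 <- NULL
    for (w in config$trend_windows) {
      tr <- window_trend(adj, w, final_year, lek_id = id)
      out[[paste0("trend", w)]] <- tr$value
      if (w == 5L) tr5 <- tr
    }
    if (is.null(tr5)) tr5 <- window_trend(adj, config$trend_windows[1],
                                          final_year, lek_id = id)
    out$adjusted_final_count <- as.numeric(adj[as.character(final_year)])
    out$binary <- binary_response(tr5)$value
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "final_year") <- final_year
  res
}

#' Write trend responses in long form
#'
#' One row per (lek, response kind): `lek_id, kind, value, window_start,
#' window_end`.
#'
#' @param responses wide table from [lek_trend_responses()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trend_responses <- function(responses, path) {
  final_year <- attr(responses, "final_year")
  kinds <- setdiff(names(responses), c("lek_id", "x", "y", "span"))
  long <- do.call(rbind, lapply(kinds, function(k) {
    w <- if (grepl("^trend[0-9]+$", k)) {
      as.integer(sub("trend", "", k))
    } else if (k == "adjusted_final_count") 1L else 5L
    data.frame(lek_id = responses$lek_id, kind = k,
               value = responses[[k]],
               window_start = final_year - w + 1L,
               window_end = final_year, stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
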