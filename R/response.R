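#' Functional response line of attendance change versus density
#'
#' Constructor for a fitted (or published) response line: attendance change
#' (males/lek/year) as an affine function of pad density (pads/km^2) for
#' one window radius and time lag.
#'
#' @param slope males/lek/year per pad/km^2.
#' @param intercept males/lek/year at zero density.
#' @param radius_km window radius the density refers to.
#' @param lag_years time lag of the density snapshot.
#' @return An object of class `response_line`.
#' @export
response_line <- function(slope, intercept, radius_km = NA_real_,
                          lag_years = NA_integer_) {
  stopifnot(is.finite(slope), is.finite(intercept))
  structure(list(slope = slope, intercept = intercept,
                 radius_km = radius_km, lag_years = as.integer(lag_years)),
            class = "response_line")
}

#' @export
print.response_line <- function(x, ...) {
  cat(sprintf(
    "<response_line> change = %.4g x density %+.4g  (%g km, lag %s y)\n",
    x$slope, x$intercept, x$radius_km,
    ifelse(is.na(x$lag_years), "?", x$lag_years)))
  invisible(x)
}

#' Fit a response line by ordinary least squares
#'
#' Regresses per-lek attendance change on per-lek pad density, giving the
#' region-level trend line used to extrapolate expected declines.
#'
#' @param densities per-lek densities (pads/km^2), >= 3 values with
#'   non-degenerate spread.
#' @param changes per-lek attendance changes (males/lek/year).
#' @param radius_km,lag_years metadata carried into the line.
#' @return A [response_line()] with `se` (slope, intercept standard
#'   errors), `r_squared` and `n` attached as attributes.
#' @export
fit_response_line <- function(densities, changes, radius_km = NA_real_,
                              lag_years = NA_integer_) {
  stopifnot(length(densities) == length(changes), length(densities) >= 3)
  if (stats::var(densities) == 0) {
    stop("density values have zero variance; slope is undefined",
         call. = FALSE)
  }
  fit <- stats::lm(changes ~ densities)
  cf <- summary(fit)$coefficients
  line <- response_line(slope = cf["densities", "Estimate"],
                        intercept = cf["(Intercept)", "Estimate"],
                        radius_km = radius_km, lag_years = lag_years)
  attr(line, "se") <- c(slope = cf["densities", "Std. Error"],
                        intercept = cf["(Intercept)", "Std. Error"])
  attr(line, "r_squared") <- summary(fit)$r.squared
  attr(line, "n") <- length(densities)
  line
}

#' Predicted attendance change at a given density
#'
#' @param line a [response_line()].
#' @param density pad density (pads/km^2, >= 0); vectorised.
#' @return Predicted change in males/lek/year (`slope * density +
#'   intercept`).
#' @examples
#' predict_change(response_line(-1.45, -3.3), 0.08)  # -3.416
#' @export
predict_change <- function(line, density) {
  stopifnot(inherits(line, "response_line"), all(density >= 0))
  line$slope * density + line$intercept
}

#' Forecast mean attendance change across response lines
#'
#' Combines the per-line predictions at the current densities into a single
#' expected statewide change.  The aggregate is the arithmetic mean of the
#' per-line predictions; the per-line vector is always returned so any
#' alternative aggregation can be recomputed from it.
#'
#' @param lines list of [response_line()]s.
#' @param current_densities named numeric vector of current densities, one
#'   per line, keys `"<radius_km>km_lag<lag>"` matching the lines' metadata.
#' @return list `per_line` (named predictions, males/lek/year) and
#'   `aggregate` (their mean).
#' @export
forecast_mean_decline <- function(lines, current_densities) {
  keys <- vapply(lines, function(l) {
    sprintf("%gkm_lag%d", l$radius_km, l$lag_years)
  }, character(1))
  miss <- setdiff(keys, names(current_densities))
  if (length(miss)) {
    stop(sprintf("no current density supplied for line(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  per <- vapply(seq_along(lines), function(i) {
    predict_change(lines[[i]], current_densities[[keys[i]]])
  }, numeric(1))
  names(per) <- keys
  list(per_line = per, aggregate = mean(per))
}

#' Sustainable development density under a response line
#'
#' The largest density at which the predicted attendance change still
#' meets `floor` (e.g. 0 males/lek/year for no decline).  Requires a
#' declining response (`slope < 0`); 0 is returned when even an
#' undeveloped landscape violates the floor.  The equivalent pad count for
#' the line's window radius is attached (via the literal count/area
#' conversion) when the radius is known.
#'
#' @param line a [response_line()] with `slope < 0`.
#' @param floor minimum acceptable change (males/lek/year), default 0.
#' @return Density in pads/km^2, with attribute `pad_count` where the
#'   radius is known.
#' @examples
#' sustainable_density(response_line(-7.7, 3.02))  # 0.3922...
#' @export
sustainable_density <- function(line, floor = 0) {
  stopifnot(inherits(line, "response_line"))
  if (line$slope >= 0) {
    stop("response is not declining (slope >= 0); threshold is unbounded",
         call. = FALSE)
  }
  d <- max(0, (floor - line$intercept) / line$slope)
  if (!is.na(line$radius_km)) {
    attr(d, "pad_count") <- density_to_count(d, line$radius_km)
  }
  d
}

#' Percent change between two totals
#'
#' Convenience for worked examples such as statewide attendance totals:
#' `100 * (new - old) / old` (negative for a decline).
#'
#' @param old,new totals.
#' @return Signed percent change.
#' @examples
#' percent_change(18631, 14185)  # -23.86...
#' @export
percent_change <- function(old, new) {
  stopifnot(old != 0)
  100 * (new - old) / old
}
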