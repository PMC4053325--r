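#' Pads active on the landscape in a given year
#'
#' A pad counts toward disturbance density in `year` when it was actually
#' drilled (`start_year` present and `<= year`), has not ceased activity
#' (`end_year` absent or `>= year`), and its classification does not mark it
#' as permit-only (`"AP"`: a permit to drill with no record that drilling
#' ever occurred).  Dry-hole or dormant pads carry the year activity ceased
#' in `end_year` and so drop out of later years via the interval rule.
#'
#' @param pads a [pad_table].
#' @param year integer query year.
#' @return The active subset of `pads` (still a `pad_table`).
#' @export
filter_active_pads <- function(pads, year) {
  stopifnot(inherits(pads, "pad_table"), length(year) == 1)
  year <- as.integer(year)
  keep <- !is.na(pads$start_year) & pads$start_year <= year &
    (is.na(pads$end_year) | pads$end_year >= year) &
    pads$class != "AP"
  out <- pads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Roving-window point density of active pads around leks
#'
#' For each lek, counts active pads within a closed disc of radius
#' `radius_km` (a pad at exactly the radius is included) and divides by the
#' full disc area.  No edge correction is applied: discs crossing the study
#' extent are still normalised by \eqn{\pi r^2}, mirroring standard GIS
#' point-density semantics.
#'
#' @param pads a [pad_table].
#' @param centers data.frame with columns `lek_id`, `x`, `y` (one row per
#'   lek; a [lek_table] is accepted and reduced to unique leks).
#' @param radius_km positive radius in kilometres.
#' @param year integer; pads are filtered for activity in this year.
#' @return data.frame with columns `lek_id`, `radius_km`, `reference_year`,
#'   `density` (pads/km^2).
#' @examples
#' pads <- pad_table(c("a", "b", "c"), c(0, 1000, 5000), 0, start_year = 2000)
#' ctr <- data.frame(lek_id = "L", x = 0, y = 0)
#' roving_density(pads, ctr, radius_km = 2, year = 2005)$density  # 2/(pi*4)
#' @export
roving_density <- function(pads, centers, radius_km, year) {
  stopifnot(length(radius_km) == 1, radius_km > 0)
  centers <- unique(as.data.frame(centers)[c("lek_id", "x", "y")])
  act <- filter_active_pads(pads, year)
  r_m <- radius_km * 1000
  counts <- if (nrow(act) == 0) {
    rep(0L, nrow(centers))
  } else {
    vapply(seq_len(nrow(centers)), function(i) {
      d2 <- (act$x - centers$x[i])^2 + (act$y - centers$y[i])^2
      sum(d2 <= r_m^2)
    }, integer(1))
  }
  data.frame(
    lek_id = centers$lek_id, radius_km = radius_km,
    reference_year = as.integer(year),
    density = counts / (pi * radius_km^2),
    stringsAsFactors = FALSE
  )
}

#' Multi-scale lagged density covariate matrix
#'
#' Builds the design covariates for the spatial regressions: one column per
#' (radius, lag) pair holding the roving-window density at that radius,
#' evaluated in the reference year `window_start_year - lag`.  Columns are
#' ordered radius-major, lag-minor and named `d_<radius>km_lag<lag>`.
#'
#' @param leks a [lek_table] (or data.frame with `lek_id`, `x`, `y`).
#' @param pads a [pad_table].
#' @param config an [analysis_config] supplying `radii_km` and `lag_years`.
#' @param window_start_year integer; first year of the trend window the
#'   lagged densities are referenced against.
#' @param history_start_year optional integer; if given, the earliest lagged
#'   reference year must not precede it (configuration error otherwise).
#' @return data.frame: `lek_id`, `x`, `y`, then one density column per
#'   (radius, lag), with a `reference_years` attribute.
#' @export
density_matrix <- function(leks, pads, config, window_start_year,
                           history_start_year = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  window_start_year <- as.integer(window_start_year)
  ref_years <- window_start_year - config$lag_years
  if (!is.null(history_start_year) && min(ref_years) < history_start_year) {
    stop(sprintf(
      "pad history starts %d but lag %d needs reference year %d",
      history_start_year, max(config$lag_years), min(ref_years)),
      call. = FALSE)
  }
  centers <- unique(as.data.frame(leks)[c("lek_id", "x", "y")])
  out <- centers
  refs <- integer(0)
  for (r in config$radii_km) {
    for (i in seq_along(config$lag_years)) {
      dc <- roving_density(pads, centers, r, ref_years[i])
      col <- sprintf("d_%gkm_lag%d", r, config$lag_years[i])
      out[[col]] <- dc$density[match(centers$lek_id, dc$lek_id)]
      refs[col] <- ref_years[i]
    }
  }
  attr(out, "reference_years") <- refs
  out
}

#' Convert between pad counts and window densities
#'
#' The literal count/area relationship for a disc of radius `radius_km`:
#' `density = n / (pi * radius_km^2)` and its inverse.  Exposed so threshold
#' densities can be read as pad counts (and vice versa) under an explicit,
#' reproducible convention.
#'
#' @param n_pads non-negative pad count.
#' @param d density in pads/km^2.
#' @param radius_km positive disc radius in kilometres.
#' @return A density (pads/km^2) or a (generally non-integer) pad count.
#' @examples
#' count_to_density(3, 2)        # 0.2387
#' density_to_count(0.7, 10)     # 219.9
#' @export
count_to_density <- function(n_pads, radius_km) {
  stopifnot(all(n_pads >= 0), all(radius_km > 0))
  n_pads / (pi * radius_km^2)
}

#' @rdname count_to_density
#' @export
density_to_count <- function(d, radius_km) {
  stopifnot(all(d >= 0), all(radius_km > 0))
  d * pi * radius_km^2
}
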