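#' Regular grid surface
#'
#' A simple raster: `origin` is the lower-left corner (metres), cells are
#' square with side `cell_size`, and `values` is an `nrows x ncols` matrix
#' whose row 1 is the TOP row of the grid (map order).  `NA` encodes
#' no-data; the ESRI ASCII writer maps it to the sentinel -9999.
#'
#' @param origin numeric `c(x, y)` of the lower-left corner.
#' @param cell_size cell side in metres.
#' @param values matrix of cell values (row 1 = top row).
#' @return An object of class `lek_surface`.
#' @export
lek_surface <- function(origin, cell_size, values) {
  stopifnot(length(origin) == 2, cell_size > 0, is.matrix(values))
  structure(list(origin = as.numeric(origin), cell_size = cell_size,
                 nrows = nrow(values), ncols = ncol(values),
                 values = values, nodata = -9999),
            class = "lek_surface")
}

#' @export
print.lek_surface <- function(x, ...) {
  cat("<lek_surface>", x$nrows, "x", x$ncols, "cells of",
      x$cell_size, "m; origin (", x$origin[1], ",", x$origin[2], ")\n")
  rng <- range(x$values, na.rm = TRUE)
  cat("  values in [", format(rng[1]), ",", format(rng[2]), "],",
      sum(is.na(x$values)), "no-data cells\n")
  invisible(x)
}

# cell-centre coordinates of a surface grid spec
surface_centers <- function(origin, cell_size, nrows, ncols) {
  cx <- origin[1] + (seq_len(ncols) - 0.5) * cell_size
  # row 1 is the top row
  cy <- origin[2] + (nrows - seq_len(nrows) + 0.5) * cell_size
  list(x = cx, y = cy)
}

#' Leks with a significant local response
#'
#' Subsets a GWR fit to the leks whose local t-value for `covariate`
#' exceeds the two-sided critical value at level `alpha`, using
#' `n - effective_params` degrees of freedom.  Per-lek tests are reported
#' without multiple-testing correction, matching common GWR practice; set
#' `adjust = "BH"` for a Benjamini-Hochberg screen instead (expect fewer
#' leks).
#'
#' @param fit a [fit_gwr()] result.
#' @param covariate column name of the covariate of interest.
#' @param alpha two-sided significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame of significant leks: `x`, `y`, `beta`, `se`, `t`.
#' @export
significant_leks <- function(fit, covariate, alpha = 0.05,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(fit, "gwr_fit"),
            covariate %in% colnames(fit$local_beta))
  df <- max(fit$n - fit$effective_params, 1)
  tv <- fit$local_t[, covariate]
  keep <- if (adjust == "none") {
    !is.na(tv) & abs(tv) > stats::qt(1 - alpha / 2, df)
  } else {
    pv <- 2 * stats::pt(abs(tv), df, lower.tail = FALSE)
    !is.na(pv) & stats::p.adjust(pv, "BH") < alpha
  }
  data.frame(
    lek = which(keep),
    x = fit$coords[keep, 1], y = fit$coords[keep, 2],
    beta = fit$local_beta[keep, covariate],
    se = fit$local_se[keep, covariate],
    t = tv[keep], stringsAsFactors = FALSE
  )
}

#' Inverse distance weighted interpolation
#'
#' Interpolates point values onto a regular grid:
#' \deqn{\hat v(c) = \sum_i v_i d_i^{-p} / \sum_i d_i^{-p}}
#' over all sample points, with a cell whose centre coincides with a sample
#' point taking that point's value exactly.  Being a convex combination,
#' every interpolated cell lies within `[min(values), max(values)]`.
#'
#' @param points two-column matrix/data.frame of sample coordinates (m).
#' @param values numeric sample values, one per point.
#' @param grid_spec list with `origin` (`c(x, y)` lower-left), `cell_size`
#'   (m), `nrows`, `ncols`; see [surface_grid_spec()] to derive one from
#'   the points.
#' @param power positive IDW exponent (2 is the conventional default).
#' @return A [lek_surface()] (all no-data if `points` is empty).
#' @export
idw_interpolate <- function(points, values, grid_spec, power = 2) {
  stopifnot(power > 0)
  pts <- as.matrix(as.data.frame(points))
  vals <- matrix(NA_real_, grid_spec$nrows, grid_spec$ncols)
  if (nrow(pts) == 0) {
    return(lek_surface(grid_spec$origin, grid_spec$cell_size, vals))
  }
  stopifnot(length(values) == nrow(pts))
  ctr <- surface_centers(grid_spec$origin, grid_spec$cell_size,
                         grid_spec$nrows, grid_spec$ncols)
  for (r in seq_len(grid_spec$nrows)) {
    dx <- outer(ctr$x, pts[, 1], "-")            # ncols x npts
    d <- sqrt(dx^2 + outer(rep(ctr$y[r], length(ctr$x)), pts[, 2], "-")^2)
    hit <- d < 1e-9
    wt <- d^(-power)
    est <- rowSums(wt * rep(values, each = nrow(wt))) / rowSums(wt)
    exact <- which(rowSums(hit) > 0)
    for (j in exact) est[j] <- values[which(hit[j, ])[1]]
    vals[r, ] <- est
  }
  lek_surface(grid_spec$origin, grid_spec$cell_size, vals)
}

#' Grid specification covering a set of points
#'
#' Builds the `grid_spec` for [idw_interpolate()]: the bounding box of the
#' points padded by `pad_m` on each side, discretised into square cells.
#'
#' @param points two-column matrix/data.frame of coordinates (m).
#' @param cell_size cell side (m).
#' @param pad_m padding added on every side (e.g. one kernel bandwidth).
#' @return list with `origin`, `cell_size`, `nrows`, `ncols`.
#' @export
surface_grid_spec <- function(points, cell_size, pad_m = 0) {
  pts <- as.matrix(as.data.frame(points))
  stopifnot(nrow(pts) >= 1, cell_size > 0, pad_m >= 0)
  xr <- range(pts[, 1]) + c(-pad_m, pad_m)
  yr <- range(pts[, 2]) + c(-pad_m, pad_m)
  list(origin = c(xr[1], yr[1]), cell_size = cell_size,
       nrows = max(1L, as.integer(ceiling(diff(yr) / cell_size))),
       ncols = max(1L, as.integer(ceiling(diff(xr) / cell_size))))
}

#' Regional summary of significant leks
#'
#' Arithmetic means of pad density and response rate over a subset of leks
#' (the caption-style numbers attached to a mapped response region).
#'
#' @param subset data.frame of leks with a `beta` or `rate` column holding
#'   the response rate (males/lek/year) and a `lek_id` or `lek` key.
#' @param densities data.frame with matching key and a `density` column
#'   (pads/km^2).
#' @return list `mean_density`, `mean_rate`, `n`; an explicit empty summary
#'   (`n = 0`, means `NA`) for an empty subset.
#' @export
region_summary <- function(subset, densities) {
  if (nrow(subset) == 0) {
    return(list(mean_density = NA_real_, mean_rate = NA_real_, n = 0L))
  }
  key <- if ("lek_id" %in% names(subset)) "lek_id" else "lek"
  rate <- if ("rate" %in% names(subset)) subset$rate else subset$beta
  d <- densities$density[match(subset[[key]], densities[[key]])]
  list(mean_density = mean(d), mean_rate = mean(rate),
       n = nrow(subset))
}

#' Lek pairs with matched density but opposing responses
#'
#' Finds pairs of leks whose development densities agree within a relative
#' tolerance yet whose attendance trends have opposite signs — the
#' "identical density, opposite response" cases that show density alone
#' does not determine lek fate.  Matching is greedy and deterministic:
#' increasing leks are taken in `lek_id` order and each is paired with the
#' unused decreasing lek of closest density; each lek appears in at most
#' one pair.
#'
#' @param responses data.frame with `lek_id` and `trend` (males/lek/year).
#' @param densities data.frame with `lek_id` and `density` (pads/km^2).
#' @param tolerance relative density tolerance (default 0.05 = 5%):
#'   densities `d1`, `d2` match when `|d1 - d2| <= tolerance * max(d1, d2)`.
#' @return data.frame of pairs: ids, densities and trends of both members;
#'   zero rows when no opposing pair matches.
#' @export
opposing_response_pairs <- function(responses, densities, tolerance = 0.05) {
  stopifnot(tolerance >= 0)
  d <- densities$density[match(responses$lek_id, densities$lek_id)]
  up <- responses[responses$trend > 0, , drop = FALSE]
  up <- up[order(up$lek_id), , drop = FALSE]
  down <- responses[responses$trend < 0, , drop = FALSE]
  d_up <- d[match(up$lek_id, responses$lek_id)]
  d_down <- d[match(down$lek_id, responses$lek_id)]
  used <- rep(FALSE, nrow(down))
  out <- list()
  for (i in seq_len(nrow(up))) {
    if (!any(!used)) break
    cand <- which(!used)
    gap <- abs(d_down[cand] - d_up[i])
    j <- cand[which.min(gap)]
    lim <- tolerance * max(d_up[i], d_down[j])
    if (abs(d_down[j] - d_up[i]) <= lim) {
      used[j] <- TRUE
      out[[length(out) + 1]] <- data.frame(
        lek_up = up$lek_id[i], density_up = d_up[i], trend_up = up$trend[i],
        lek_down = down$lek_id[j], density_down = d_down[j],
        trend_down = down$trend[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(lek_up = character(), density_up = numeric(),
                      trend_up = numeric(), lek_down = character(),
                      density_down = numeric(), trend_down = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text `.asc` raster interchange: a six-line header (`ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value`) followed by rows of cell
#' values, top row first.  `NA` cells are written as -9999.
#'
#' @param surface a [lek_surface()].
#' @param path file path.
#' @return `write_esri_ascii()` returns `path` invisibly;
#'   `read_esri_ascii()` returns a [lek_surface()].
#' @export
write_esri_ascii <- function(surface, path) {
  stopifnot(inherits(surface, "lek_surface"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", surface$ncols),
    sprintf("nrows %d", surface$nrows),
    sprintf("xllcorner %.10g", surface$origin[1]),
    sprintf("yllcorner %.10g", surface$origin[2]),
    sprintf("cellsize %.10g", surface$cell_size),
    sprintf("NODATA_value %d", as.integer(surface$nodata))
  ), con)
  v <- surface$values
  v[is.na(v)] <- surface$nodata
  for (r in seq_len(surface$nrows)) {
    writeLines(paste(format(v[r, ], digits = 17, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_esri_ascii
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  get <- function(key) {
    for (h in hdr) if (h[1] == key) return(as.numeric(h[2]))
    stop(sprintf("missing ESRI ASCII header field '%s'", key), call. = FALSE)
  }
  ncols <- get("ncols"); nrows <- get("nrows")
  vals <- matrix(scan(text = paste(lines[-(1:6)], collapse = "\n"),
                      quiet = TRUE), nrow = nrows, ncol = ncols,
                 byrow = TRUE)
  nodata <- get("nodata_value")
  vals[vals == nodata] <- NA_real_
  lek_surface(c(get("xllcorner"), get("yllcorner")), get("cellsize"), vals)
}
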