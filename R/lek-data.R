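#' Construct a lek survey table
#'
#' A lek table holds one row per surveyed lek-year: the lek identifier, its
#' projected planar coordinates (metres), the survey year, the peak number of
#' displaying males counted that season, and the activity status recorded by
#' the observer.  Years absent from the table are unsurveyed years; a
#' surveyed-but-inactive lek contributes an observed count of 0, which is how
#' trend analyses treat it.
#'
#' @param lek_id character lek identifiers.
#' @param x,y projected planar coordinates in metres (constant within a lek).
#' @param year integer survey years.
#' @param males non-negative peak male counts (integers for observed data;
#'   noiseless simulated expectations may be real-valued).
#' @param status per-year activity status: `"active"`, `"inactive"` or
#'   `"unknown"`.
#'
#' @return A `data.frame` of class `lek_table`, sorted by lek then year.
#' @examples
#' lek_table("L1", 1000, 2000, year = 2010:2011, males = c(12L, 9L))
#' @export
lek_table <- function(lek_id, x, y, year, males,
                      status = rep("unknown", length(year))) {
  df <- data.frame(
    lek_id = as.character(lek_id), x = as.numeric(x), y = as.numeric(y),
    year = as.integer(year), males = as.numeric(males),
    status = as.character(status), stringsAsFactors = FALSE
  )
  validate_lek_table(df)
}

validate_lek_table <- function(df, rows = seq_len(nrow(df))) {
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i)) {
      stop(sprintf("invalid lek table: %s at row(s) %s", what,
                   paste(utils::head(rows[i], 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad(!is.finite(df$x) | !is.finite(df$y), "non-finite coordinate")
  bad(is.na(df$year), "missing year")
  bad(is.na(df$males) | df$males < 0, "missing or negative male count")
  bad(!df$status %in% c("active", "inactive", "unknown"),
      "status not one of active/inactive/unknown")
  bad(duplicated(df[c("lek_id", "year")]), "duplicated lek-year")
  # coordinates must be constant within a lek
  for (id in unique(df$lek_id)) {
    sub <- df[df$lek_id == id, ]
    if (length(unique(sub$x)) > 1 || length(unique(sub$y)) > 1) {
      stop(sprintf("invalid lek table: lek '%s' has inconsistent coordinates",
                   id), call. = FALSE)
    }
  }
  df <- df[order(df$lek_id, df$year), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("lek_table", "data.frame")
  df
}

#' Construct a well-pad table
#'
#' One row per pad: identifier, projected planar coordinates (metres), the
#' agency classification and status codes, and the active interval.  A pad
#' with no `start_year` has no record of ever being drilled; an absent
#' `end_year` means activity is ongoing.
#'
#' @param pad_id character pad identifiers.
#' @param x,y projected planar coordinates in metres.
#' @param class classification code (e.g. `"AP"` = permit to drill only).
#' @param status status code (e.g. `"PR"` producing, `"DH"` dry hole).
#' @param start_year integer activation year, or `NA` if never drilled.
#' @param end_year integer year activity ceased, or `NA` if ongoing.
#'
#' @return A `data.frame` of class `pad_table`.
#' @examples
#' pad_table("P1", 500, 500, class = "PROD", status = "PR", start_year = 2001)
#' @export
pad_table <- function(pad_id, x, y, class = "PROD", status = "PR",
                      start_year = NA_integer_, end_year = NA_integer_) {
  n <- length(pad_id)
  df <- data.frame(
    pad_id = as.character(pad_id), x = as.numeric(x), y = as.numeric(y),
    class = rep_len(as.character(class), n),
    status = rep_len(as.character(status), n),
    start_year = rep_len(as.integer(start_year), n),
    end_year = rep_len(as.integer(end_year), n),
    stringsAsFactors = FALSE
  )
  validate_pad_table(df)
}

validate_pad_table <- function(df, rows = seq_len(nrow(df))) {
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i)) {
      stop(sprintf("invalid pad table: %s at row(s) %s", what,
                   paste(utils::head(rows[i], 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad(!is.finite(df$x) | !is.finite(df$y), "non-finite coordinate")
  bad(!is.na(df$start_year) & !is.na(df$end_year) &
        df$end_year < df$start_year, "end_year earlier than start_year")
  bad(duplicated(df$pad_id), "duplicated pad_id")
  rownames(df) <- NULL
  class(df) <- c("pad_table", "data.frame")
  df
}

#' Read and write lek survey tables
#'
#' Plain comma-separated files with a header row and columns `lek_id, x, y,
#' year, males, status` ('.' decimal, UTF-8).  Reading validates every row
#' and names offending rows in its error messages; writing is the exact
#' inverse, so write-then-read is the identity on valid tables.
#'
#' @param path file path.
#' @return `read_lek_table()` returns a [lek_table]; `write_lek_table()`
#'   returns `path` invisibly.
#' @export
read_lek_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("lek_id", "x", "y", "year", "males", "status")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("lek table '%s' is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(
    lek_id = df$lek_id,
    x = as.numeric(df$x), y = as.numeric(df$y),
    year = suppressWarnings(as.integer(df$year)),
    males = suppressWarnings(as.numeric(df$males)),
    status = df$status, stringsAsFactors = FALSE
  )
  # data-file rows: header is line 1
  validate_lek_table(out, rows = seq_len(nrow(out)) + 1L)
}

#' @rdname read_lek_table
#' @param leks a [lek_table].
#' @export
write_lek_table <- function(leks, path) {
  stopifnot(inherits(leks, "lek_table"))
  utils::write.csv(as.data.frame(leks), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write well-pad tables
#'
#' CSV with header columns `pad_id, x, y, class, status, start_year,
#' end_year`.  Empty `start_year`/`end_year` fields map to `NA` (absent).
#'
#' @param path file path.
#' @return `read_pad_table()` returns a [pad_table]; `write_pad_table()`
#'   returns `path` invisibly.
#' @export
read_pad_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("pad_id", "x", "y", "class", "status", "start_year", "end_year")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("pad table '%s' is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  to_int <- function(v) {
    v[!nzchar(v)] <- NA_character_
    suppressWarnings(as.integer(v))
  }
  out <- data.frame(
    pad_id = df$pad_id,
    x = as.numeric(df$x), y = as.numeric(df$y),
    class = df$class, status = df$status,
    start_year = to_int(df$start_year), end_year = to_int(df$end_year),
    stringsAsFactors = FALSE
  )
  validate_pad_table(out, rows = seq_len(nrow(out)) + 1L)
}

#' @rdname read_pad_table
#' @param pads a [pad_table].
#' @export
write_pad_table <- function(pads, path) {
  stopifnot(inherits(pads, "pad_table"))
  utils::write.csv(as.data.frame(pads), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Filter leks eligible for trend analysis
#'
#' Retains leks with enough survey coverage to support trend regressions over
#' the most recent 3, 5 and 10 years anchored at `final_year`: surveyed in
#' all of the last 3 years, in at least 4 of the last 5 years, and in at
#' least 6 of the last 10 years including the first year of the window.  All
#' three conditions are required.
#'
#' @param leks a [lek_table].
#' @param final_year integer; last year of the 10-year study window.
#' @param data_start_year optional integer giving the first year the survey
#'   programme covers; supplying it turns a window that pre-dates the data
#'   into a configuration error rather than silently rejecting every lek.
#' @return The subset of `leks` (still a `lek_table`) from eligible leks.
#' @examples
#' lk <- lek_table(rep("A", 6), 0, 0,
#'                 year = c(2002, 2005, 2007, 2009, 2010, 2011),
#'                 males = rep(5L, 6))
#' nrow(filter_eligible_leks(lk, 2011))  # retained
#' @export
filter_eligible_leks <- function(leks, final_year, data_start_year = NULL) {
  stopifnot(inherits(leks, "lek_table"), length(final_year) == 1)
  final_year <- as.integer(final_year)
  if (nrow(leks) == 0) return(leks)
  if (!is.null(data_start_year) && final_year - 9L < data_start_year) {
    stop(sprintf(
      "10-year window %d-%d extends before the first data year (%d)",
      final_year - 9L, final_year, data_start_year), call. = FALSE)
  }
  keep_id <- vapply(split(leks$year, leks$lek_id), function(yrs) {
    all((final_year - 2L):final_year %in% yrs) &&
      sum(yrs >= final_year - 4L & yrs <= final_year) >= 4L &&
      sum(yrs >= final_year - 9L & yrs <= final_year) >= 6L &&
      (final_year - 9L) %in% yrs
  }, logical(1))
  out <- leks[leks$lek_id %in% names(keep_id)[keep_id], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derived 10-year occupancy flag
#'
#' A lek is flagged occupied over the 10-year window ending at `final_year`
#' if any surveyed year in the window recorded males present or an "active"
#' status.  This management-style status is a derived descriptor only; it is
#' not one of the modelled trend responses.
#'
#' @param leks a [lek_table].
#' @param final_year integer; last year of the window.
#' @return Named logical vector, one element per lek.
#' @export
lek_occupancy <- function(leks, final_year) {
  stopifnot(inherits(leks, "lek_table"))
  final_year <- as.integer(final_year)
  win <- leks[leks$year >= final_year - 9L & leks$year <= final_year, ]
  vapply(split(win, win$lek_id),
         function(d) any(d$males > 0 | d$status == "active"),
         logical(1))
}

#' Write per-lek results as GeoJSON points
#'
#' Emits an RFC 7946 FeatureCollection with one Point feature per row of
#' `data`; all columns other than `x` and `y` become feature properties.
#' Coordinates are written as-is (projected planar metres), which is
#' adequate for interchange within one projected analysis.
#'
#' @param data data.frame with numeric `x` and `y` columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geojson_points <- function(data, path) {
  stopifnot(is.data.frame(data), all(c("x", "y") %in% names(data)))
  props <- data[setdiff(names(data), c("x", "y"))]
  features <- lapply(seq_len(nrow(data)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(data$x[i], data$y[i])),
      properties = as.list(props[i, , drop = FALSE])
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
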