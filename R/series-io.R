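# Daily site series: the per-site record of climate, hydrology and water
# temperature.  Schema (one row per day, dates contiguous):
#   date    ISO-8601 day
#   ta_max  day maximum air temperature (degC)
#   ta_min  day minimum air temperature (degC)
#   tw_max  day maximum water temperature (degC)
#   q       streamflow (m3/s, > 0)
#   level   daily median water level (m)
# Missing days are represented by rows of NA, never by absent dates.

series_columns <- c("date", "ta_max", "ta_min", "tw_max", "q", "level")

#' Validate a daily site series
#'
#' Checks the schema, date contiguity, `ta_min <= ta_max` and `q > 0` on
#' observed days.
#'
#' @param series Data frame with columns `date`, `ta_max`, `ta_min`,
#'   `tw_max`, `q`, `level`.
#' @param site_id Optional site label used in error messages.
#' @return The validated data frame (dates coerced to `Date`), invisibly
#'   classed as `daily_series`.
#' @export
validate_series <- function(series, site_id = attr(series, "site_id") %||% "?") {
  missing_cols <- setdiff(series_columns, names(series))
  if (length(missing_cols))
    stopf("series '%s': missing required column(s): %s", site_id,
          paste(missing_cols, collapse = ", "))
  series$date <- as_date(series$date)
  if (nrow(series) > 1) {
    gaps <- diff(as.integer(series$date))
    if (any(gaps != 1L)) {
      i <- which(gaps != 1L)[1]
      missing_days <- seq(series$date[i] + 1, series$date[i + 1] - 1, by = "day")
      stopf("series '%s': dates not contiguous; gap of %d day(s): %s", site_id,
            length(missing_days), paste(missing_days, collapse = ", "))
    }
  }
  obs <- !is.na(series$ta_max) & !is.na(series$ta_min)
  if (any(series$ta_min[obs] > series$ta_max[obs]))
    stopf("series '%s': ta_min exceeds ta_max on %d day(s)", site_id,
          sum(series$ta_min[obs] > series$ta_max[obs]))
  qobs <- !is.na(series$q)
  if (any(series$q[qobs] <= 0))
    stopf("series '%s': non-positive discharge on %d day(s)", site_id,
          sum(series$q[qobs] <= 0))
  attr(series, "site_id") <- site_id
  class(series) <- unique(c("daily_series", class(series)))
  invisible(series)
}

#' Read one daily site series from CSV
#'
#' @param path CSV path; the site id defaults to the file stem.
#' @param site_id Site label.
#' @return Validated `daily_series` data frame.
#' @export
read_series_csv <- function(path, site_id = sub("\\.csv$", "", basename(path))) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_series(df, site_id)
}

#' Write one daily site series to CSV
#'
#' @param series `daily_series` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_series_csv <- function(series, path) {
  df <- as.data.frame(series)[, series_columns]
  df$date <- format(as_date(df$date))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write the extreme-events table
#'
#' `events.csv` has columns `date`, `season` and optionally `anomaly` and
#' `fraction` (set by the detector, absent for externally supplied lists).
#'
#' @param path CSV path.
#' @return Data frame with `date` (`Date`) and `season`.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"date" %in% names(df)) stopf("events file %s: missing required column 'date'", path)
  df$date <- as_date(df$date)
  if (!"season" %in% names(df)) df$season <- assign_season(df$date)
  df
}

#' @rdname read_events_csv
#' @param events Events data frame.
#' @export
write_events_csv <- function(events, path) {
  events$date <- format(as_date(events$date))
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read all series of a directory
#'
#' @param dir Directory of `<site>.csv` files.
#' @return Named list of validated series.
#' @export
read_series_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stopf("no series CSVs found under %s", dir)
  out <- lapply(files, read_series_csv)
  names(out) <- vapply(out, function(s) attr(s, "site_id"), "")
  out
}
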