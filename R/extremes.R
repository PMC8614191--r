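# Extreme-date identification.  Region-wide extreme dates are found from
# water-temperature anomalies relative to a per-site seasonal baseline: a
# cyclic penalized spline on day-of-year (GCV-smoothed).  A date qualifies
# when its anomaly exceeds the site's high quantile at a minimum fraction
# of sites, and runs of qualifying days collapse to their peak day.  An
# externally supplied event list can always be used instead (bypass mode).

#' Seasonal baseline of daily maximum water temperature
#'
#' Fits a cyclic penalized regression spline (mgcv, GCV smoothing) on
#' day-of-year to at least one full year of daily maxima and returns the
#' baseline and residuals.
#'
#' @param series A `daily_series` data frame (>= 365 days with data).
#' @param k Spline basis dimension (default 12).
#' @return List with `baseline` and `residual` vectors aligned to
#'   `series$date`.
#' @export
fit_seasonal_baseline <- function(series, k = 12) {
  ok <- !is.na(series$tw_max)
  if (sum(ok) < 365)
    stopf("fit_seasonal_baseline: need at least one full year of data (%d days available)",
          sum(ok))
  doy <- as.integer(format(series$date, "%j"))
  doy[doy == 366] <- 365
  df <- data.frame(tw = series$tw_max, doy = doy)
  fit <- mgcv::gam(tw ~ s(doy, bs = "cc", k = k), data = df[ok, ],
                   method = "GCV.Cp", knots = list(doy = c(0.5, 365.5)))
  baseline <- as.numeric(mgcv::predict.gam(fit, newdata = data.frame(doy = doy)))
  list(baseline = baseline, residual = series$tw_max - baseline)
}

#' Detect region-wide extreme dates
#'
#' @param series_list Named list of `daily_series`.
#' @param q Per-site residual quantile that defines "extreme" (in
#'   `(0.5, 1)`).
#' @param min_site_fraction Minimum fraction of sites that must exceed
#'   their threshold on a date (in `[0, 1]`).
#' @param min_anomaly Absolute anomaly floor (degC, default 4): a site only
#'   counts as exceeding when its residual also tops this value, so that
#'   ordinary weather noise (and, at the limit, the numerically tiny
#'   departures of a clean seasonal cycle) is never flagged as regionally
#'   extreme.
#' @param k Baseline basis dimension (see [fit_seasonal_baseline()]).
#' @return Data frame of extreme dates: `date`, `season`, `anomaly` (mean
#'   exceeding-site anomaly, degC) and `fraction` of sites exceeding.
#' @export
detect_extremes <- function(series_list, q = 0.97, min_site_fraction = 0.5,
                            min_anomaly = 4, k = 12) {
  if (!length(series_list)) stopf("detect_extremes: no series supplied")
  if (!is_number(q) || q <= 0.5 || q >= 1)
    stopf("detect_extremes: quantile q must lie in (0.5, 1)")
  if (min_site_fraction < 0 || min_site_fraction > 1)
    stopf("detect_extremes: min_site_fraction must lie in [0, 1]")
  dates <- series_list[[1]]$date
  res <- sapply(series_list, function(s) fit_seasonal_baseline(s, k = k)$residual)
  thr <- apply(res, 2, stats::quantile, probs = q, na.rm = TRUE)
  exceed <- sweep(res, 2, pmax(thr, min_anomaly), ">")
  frac <- rowMeans(exceed, na.rm = TRUE)
  qualifies <- frac >= max(min_site_fraction, 1e-12) & frac > 0
  if (!any(qualifies)) {
    return(data.frame(date = as.Date(character(0)), season = character(0),
                      anomaly = numeric(0), fraction = numeric(0)))
  }
  # collapse runs of consecutive qualifying days to their peak day
  idx <- which(qualifies)
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  mean_anom <- rowMeans(ifelse(exceed, res, NA), na.rm = TRUE)
  peaks <- vapply(runs, function(r) r[which.max(mean_anom[r])], 0L)
  out <- data.frame(
    date = dates[peaks],
    season = assign_season(dates[peaks]),
    anomaly = mean_anom[peaks],
    fraction = frac[peaks]
  )
  rownames(out) <- NULL
  ts_log("detect_extremes: %d extreme date(s) at q = %.3f, f = %.2f",
         nrow(out), q, min_site_fraction)
  out
}
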