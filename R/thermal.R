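#' Extract the 15-day window around an extreme date
#'
#' The thermal-dynamics model is fitted over the period from 7 days before
#' to 7 days after an extreme date.  Windows that would extend beyond the
#' series, or that contain missing days, are refused.
#'
#' @param series A validated `daily_series` data frame.
#' @param extreme_date The extreme date.
#' @return A data frame of exactly 15 rows (class `event_window`), with
#'   attributes `site_id` and `event_date`.
#' @export
extract_window <- function(series, extreme_date) {
  extreme_date <- as_date(extreme_date)
  i <- match(extreme_date, series$date)
  if (is.na(i) || i < 8 || i > nrow(series) - 7)
    stopf("window unavailable: %s needs 7 days of margin inside %s..%s",
          extreme_date, min(series$date), max(series$date))
  w <- series[(i - 7):(i + 7), , drop = FALSE]
  need <- c("ta_max", "ta_min", "tw_max", "q")
  if (anyNA(w[, need]))
    stopf("window at %s refused: missing values on %d day(s)",
          extreme_date, sum(!stats::complete.cases(w[, need])))
  attr(w, "site_id") <- attr(series, "site_id")
  attr(w, "event_date") <- extreme_date
  class(w) <- c("event_window", "data.frame")
  w
}

#' Fit the thermal-dynamics model to one event window
#'
#' Fits the daily model of water-temperature dynamics around an extreme
#' event,
#' \deqn{\Delta T_w[t] = \frac{a (T_{aM}[t] - T_w[t]) + b (T_{am}[t] - T_w[t])}{Q[t]} + c,}
#' where \eqn{a} is the day thermal sensitivity (response of water
#' temperature to day maximum air temperature), \eqn{b} the night thermal
#' sensitivity and \eqn{c} a non-convective flux term absorbing processes
#' other than air-water convection (e.g. advection).  The default
#' (`mode = "derivative"`) regresses the daily forward difference of water
#' temperature on the two convective regressors evaluated at day `t` by
#' ordinary least squares, which exactly inverts the forward-Euler
#' generator; `mode = "trajectory"` instead minimises the squared error of
#' the forward-integrated trajectory started from the observed first day.
#'
#' @param window An [extract_window()] result (15 contiguous complete days).
#' @param mode `"derivative"` (default) or `"trajectory"`.
#' @return An object of class `thermal_fit` with components `coefficients`
#'   (`a`, `b`, `c`), `n_obs`, `rss`, `r_squared`, `se`, `site_id`,
#'   `event_date`, `mode` and the fitted `window`.
#' @export
#' @examples
#' w <- data.frame(date = as.Date("2015-07-01") + 0:14,
#'                 ta_max = 25 + sin(1:15), ta_min = 15 + sin(1:15),
#'                 tw_max = NA, q = 5, level = 0.4)
#' w$tw_max <- simulate_water_temperature(w, w, c(a = 2, b = 1, c = 0.1))
#' ww <- extract_window(validate_series(w, "demo"), w$date[8])
#' coef(thermal_model(ww))
thermal_model <- function(window, mode = c("derivative", "trajectory")) {
  mode <- match.arg(mode)
  stopifnot(nrow(window) >= 3)
  tw <- window$tw_max; ta_M <- window$ta_max; ta_m <- window$ta_min; q <- window$q
  n <- nrow(window)
  t_idx <- seq_len(n - 1)
  dtw <- diff(tw)
  x1 <- (ta_M[t_idx] - tw[t_idx]) / q[t_idx]
  x2 <- (ta_m[t_idx] - tw[t_idx]) / q[t_idx]
  X <- cbind(x1 = x1, x2 = x2, intercept = 1)
  if (qr(X)$rank < 3)
    stopf("degenerate fit: design is rank-deficient (air and water temperatures do not separate a, b, c)")
  fit <- stats::lm(dtw ~ x1 + x2)
  cf <- stats::coef(fit)
  coefs <- c(a = unname(cf["x1"]), b = unname(cf["x2"]), c = unname(cf["(Intercept)"]))
  if (mode == "trajectory") {
    target <- function(p) {
      sim <- numeric(n); sim[1] <- tw[1]
      for (t in seq_len(n - 1)) {
        sim[t + 1] <- sim[t] + (p[1] * (ta_M[t] - sim[t]) + p[2] * (ta_m[t] - sim[t])) / q[t] + p[3]
      }
      sum((sim - tw)^2)
    }
    opt <- stats::optim(coefs, target, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    coefs <- c(a = opt$par[[1]], b = opt$par[[2]], c = opt$par[[3]])
  }
  if (any(!is.finite(coefs))) stopf("degenerate fit: non-finite coefficient estimates")
  res <- dtw - (coefs["a"] * x1 + coefs["b"] * x2 + coefs["c"])
  rss <- sum(res^2)
  tss <- sum((dtw - mean(dtw))^2)
  structure(list(
    coefficients = coefs,
    n_obs = length(dtw),
    rss = rss,
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    se = if (mode == "derivative") suppressWarnings(summary(fit))$coefficients[c("x1", "x2", "(Intercept)"), 2] else rep(NA_real_, 3),
    negative_sensitivity = unname(coefs["a"] < 0 | coefs["b"] < 0),
    site_id = attr(window, "site_id"),
    event_date = attr(window, "event_date"),
    mode = mode,
    window = window
  ), class = "thermal_fit")
}

#' @export
coef.thermal_fit <- function(object, ...) object$coefficients

#' @export
print.thermal_fit <- function(x, ...) {
  cat(sprintf("Thermal-dynamics fit (%s), site %s, event %s\n", x$mode,
              x$site_id %||% "?", format(x$event_date %||% NA)))
  cat(sprintf("  a (day sensitivity)   %8.4f\n", x$coefficients["a"]))
  cat(sprintf("  b (night sensitivity) %8.4f\n", x$coefficients["b"]))
  cat(sprintf("  c (non-convective)    %8.4f degC/day\n", x$coefficients["c"]))
  cat(sprintf("  n = %d daily steps, RSS = %.4g, window R2 = %.3f\n",
              x$n_obs, x$rss, x$r_squared))
  if (isTRUE(x$negative_sensitivity)) cat("  note: negative sensitivity estimate\n")
  invisible(x)
}

#' @export
summary.thermal_fit <- function(object, ...) {
  out <- data.frame(
    estimate = object$coefficients,
    se = object$se,
    row.names = c("a", "b", "c")
  )
  structure(list(table = out, fit = object), class = "summary.thermal_fit")
}

#' @export
print.summary.thermal_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  print(x$table)
  invisible(x)
}

#' @export
residuals.thermal_fit <- function(object, ...) {
  w <- object$window
  n <- nrow(w)
  t_idx <- seq_len(n - 1)
  cf <- object$coefficients
  diff(w$tw_max) - (cf["a"] * (w$ta_max[t_idx] - w$tw_max[t_idx]) +
                      cf["b"] * (w$ta_min[t_idx] - w$tw_max[t_idx])) / w$q[t_idx] - cf["c"]
}

#' Predicted water-temperature trajectory
#'
#' Forward-integrates the fitted model from the first observed day over the
#' fitted window (or over `newdata`: a data frame with `ta_max`, `ta_min`,
#' `q` and an initial `tw_max[1]`).
#'
#' @param object A `thermal_fit`.
#' @param newdata Optional forcing data frame.
#' @param ... Unused.
#' @return Numeric vector of daily water temperature.
#' @export
predict.thermal_fit <- function(object, newdata = NULL, ...) {
  w <- newdata %||% object$window
  cf <- object$coefficients
  # forward-integrate, anchored at the observed first day
  sim <- numeric(nrow(w)); sim[1] <- w$tw_max[1]
  for (t in seq_len(nrow(w) - 1)) {
    sim[t + 1] <- sim[t] + (cf["a"] * (w$ta_max[t] - sim[t]) +
                              cf["b"] * (w$ta_min[t] - sim[t])) / w$q[t] + cf["c"]
  }
  sim
}

#' Simulate new windows from a fitted thermal model
#'
#' @param object A `thermal_fit`.
#' @param nsim Number of simulated trajectories.
#' @param seed Optional seed.
#' @param obs_sd Observation noise sd (degC); defaults to the residual sd.
#' @param ... Unused.
#' @return A matrix (days x nsim) of simulated water temperatures.
#' @export
simulate.thermal_fit <- function(object, nsim = 1, seed = NULL, obs_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(obs_sd)) obs_sd <- sqrt(object$rss / max(1, object$n_obs - 3))
  base <- predict(object)
  vapply(seq_len(nsim), function(i) base + stats::rnorm(length(base), 0, obs_sd),
         numeric(length(base)))
}

#' @export
plot.thermal_fit <- function(x, ...) {
  w <- x$window
  graphics::plot(w$date, w$tw_max, type = "b", pch = 16,
                 xlab = "date", ylab = "day max water temperature (degC)",
                 main = sprintf("site %s, event %s", x$site_id %||% "?",
                                format(x$event_date %||% NA)), ...)
  graphics::lines(w$date, predict(x), col = 2, lwd = 2)
  graphics::abline(v = as.numeric(x$event_date), lty = 3)
  graphics::legend("topleft", c("observed", "fitted"), col = c(1, 2),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Fit the thermal model to every site and extreme date
#'
#' Applies [extract_window()] and [thermal_model()] to every (site, date)
#' pair; pairs whose window is unavailable or degenerate are skipped and
#' logged, never aborting the batch.
#'
#' @param series_list Named list of `daily_series` (one per site).
#' @param extreme_dates `Date` vector of extreme dates.
#' @param mode Fit mode passed to [thermal_model()].
#' @return Data frame with one row per successful fit: `site_id`, `date`,
#'   `a`, `b`, `c`, `n_obs`, `rss`, `r2`; skipped pairs are recorded in the
#'   `skips` attribute.
#' @export
fit_all_events <- function(series_list, extreme_dates, mode = "derivative") {
  extreme_dates <- as_date(extreme_dates)
  rows <- list(); skips <- list()
  for (sid in names(series_list)) {
    for (d in as.list(extreme_dates)) {
      fit <- tryCatch({
        w <- extract_window(series_list[[sid]], d)
        thermal_model(w, mode = mode)
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        skips[[length(skips) + 1]] <- data.frame(site_id = sid, date = d,
                                                 reason = conditionMessage(fit))
        next
      }
      cf <- coef(fit)
      rows[[length(rows) + 1]] <- data.frame(
        site_id = sid, date = d, a = cf[["a"]], b = cf[["b"]], c = cf[["c"]],
        n_obs = fit$n_obs, rss = fit$rss, r2 = fit$r_squared)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = character(0), date = as.Date(character(0)),
               a = numeric(0), b = numeric(0), c = numeric(0),
               n_obs = integer(0), rss = numeric(0), r2 = numeric(0))
  skips <- if (length(skips)) do.call(rbind, skips) else NULL
  if (!is.null(skips))
    ts_log("fit_all_events: %d fit(s) skipped (%d attempted)", nrow(skips),
           length(series_list) * length(extreme_dates))
  attr(out, "skips") <- skips
  out
}

#' Aggregate fits and time-varying covariates per site over summer events
#'
#' One row per site: the mean of `a`, `b`, `c` over the summer extreme
#' events, plus the mean water LEVEL at those dates taken from the series.
#' Sites without a single valid summer fit are excluded with a warning.
#'
#' @param fits Output of [fit_all_events()].
#' @param series_list Named list of `daily_series`.
#' @param extreme_dates Summer extreme dates used for the means.
#' @return Data frame `site_id`, `a`, `b`, `c`, `LEVEL`, `n_events`.
#' @export
aggregate_summer <- function(fits, series_list, extreme_dates) {
  extreme_dates <- as_date(extreme_dates)
  summer <- fits[fits$date %in% extreme_dates, , drop = FALSE]
  out <- list()
  for (sid in names(series_list)) {
    f <- summer[summer$site_id == sid, , drop = FALSE]
    if (!nrow(f)) {
      warnf("aggregate_summer: site '%s' has no valid summer fit; excluded", sid)
      next
    }
    ser <- series_list[[sid]]
    lev <- mean(ser$level[ser$date %in% extreme_dates], na.rm = TRUE)
    out[[length(out) + 1]] <- data.frame(
      site_id = sid, a = mean(f$a), b = mean(f$b), c = mean(f$c),
      LEVEL = lev, n_events = nrow(f))
  }
  do.call(rbind, out)
}
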