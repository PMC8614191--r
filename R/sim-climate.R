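#' Generate daily air-temperature series
#'
#' Regional seasonal sinusoid (peaking in late July) plus regional AR(1)
#' noise shared by all sites, a small per-site iid component, and additive
#' triangular heat-wave anomalies at the scheduled dates.  The day minimum
#' is the day maximum minus a stochastic (but positive) diurnal range, so
#' `ta_min <= ta_max` by construction; heat waves are applied to both with
#' a damped amplitude at night.
#'
#' @param config A [sim_config()].
#' @param network `river_network` (site list).
#' @param seed Optional override.
#' @return Named list (per site) of data frames `date`, `ta_max`, `ta_min`.
#' @export
generate_climate <- function(config, network, seed = config$seed) {
  set.seed(child_seed(seed, "climate"))
  dates <- seq(config$start, config$end, by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- config$air_mean + config$air_amplitude * cos(2 * pi * (doy - 201) / 365.25)

  innov_sd <- config$air_ar1_sd * sqrt(1 - config$air_ar1_phi^2)
  e <- stats::filter(stats::rnorm(n, 0, innov_sd), config$air_ar1_phi,
                     method = "recursive")
  e <- as.numeric(e)

  wave <- numeric(n)
  hw <- config$heat_wave_schedule
  for (i in seq_len(nrow(hw))) {
    centre <- which(dates == hw$date[i])
    half <- (hw$duration[i] - 1) / 2
    span <- max(1, centre - ceiling(half)):min(n, centre + ceiling(half))
    wgt <- pmax(0, 1 - abs(span - centre) / (half + 1))
    wave[span] <- wave[span] + hw$amplitude[i] * wgt
    # the scheduled wave *is* the synoptic state of those days: damp the
    # free-running AR anomaly accordingly instead of stacking on top of it
    e[span] <- e[span] * (1 - wgt)
  }

  rng_reg <- pmax(2, config$diurnal_range_mean +
                    stats::rnorm(n, 0, config$diurnal_range_sd))

  out <- list()
  for (sid in network$sites$site_id) {
    site_noise <- stats::rnorm(n, 0, config$air_site_sd)
    site_rng <- pmax(1.5, rng_reg + stats::rnorm(n, 0, config$diurnal_range_sd / 2))
    ta_max <- seasonal + e + wave + site_noise
    ta_min <- ta_max - site_rng
    out[[sid]] <- data.frame(date = dates, ta_max = ta_max, ta_min = ta_min)
  }
  attr(out, "wave") <- wave
  out
}

#' Generate daily discharge and water level
#'
#' Per-site constant baseflow plus storm quickflow: storms arrive on shared
#' regional dates (Bernoulli per day), each adding an exponentially
#' distributed pulse that recesses at `storm_decay` per day; the pulse
#' volume is scaled so that the mean quickflow volume is `quickflow_share`
#' times the baseflow volume.  `quickflow_share = 0` gives constant flow
#' (BFI 1); raising it lowers the baseflow index.  Water level follows the
#' rating `level = k * Q^0.4` with a per-site coefficient.
#'
#' @param config A [sim_config()].
#' @param network `river_network`.
#' @param seed Optional override.
#' @return Named list (per site) of data frames `date`, `q`, `level`.
#' @export
generate_discharge <- function(config, network, seed = config$seed) {
  set.seed(child_seed(seed, "discharge"))
  dates <- seq(config$start, config$end, by = "day")
  n <- length(dates)
  storm_day <- stats::runif(n) < config$storm_rate
  # heat waves are dry anticyclonic spells: no storm arrivals around the
  # scheduled wave dates, so the waves remain observable in the water
  for (i in seq_len(nrow(config$heat_wave_schedule))) {
    d <- config$heat_wave_schedule$date[i]
    half <- ceiling(config$heat_wave_schedule$duration[i] / 2)
    storm_day[abs(as.integer(dates - d)) <= half + 2] <- FALSE
  }
  # expected steady-state quickflow per unit pulse mean: rate/decay
  out <- list()
  for (sid in network$sites$site_id) {
    qb <- stats::runif(1, config$baseflow_range[1], config$baseflow_range[2])
    # mean pulse size such that E[quickflow] = share * qb
    pulse_mean <- if (any(storm_day)) {
      config$quickflow_share * qb * config$storm_decay / config$storm_rate
    } else 0
    pulses <- numeric(n)
    pulses[storm_day] <- stats::rexp(sum(storm_day), rate = 1 / max(pulse_mean, 1e-12))
    if (pulse_mean == 0) pulses[] <- 0
    qf <- as.numeric(stats::filter(pulses, exp(-config$storm_decay),
                                   method = "recursive"))
    q <- pmax(qb + qf, 1e-6)
    k <- stats::runif(1, config$level_k_range[1], config$level_k_range[2])
    out[[sid]] <- data.frame(date = dates, q = q, level = k * q^0.4)
  }
  out
}

#' Simulate daily maximum water temperature
#'
#' Forward daily stepping of the thermal-dynamics model: `T_w[t+1] = T_w[t]
#' + (a (T_aM[t] - T_w[t]) + b (T_am[t] - T_w[t])) / Q[t] + c`, started at
#' the local fixed point, with optional Gaussian observation noise.  A
#' configuration whose step gain `(a + b) / Q` exceeds 2 on any day is
#' numerically unstable under the daily step and is rejected.
#'
#' @param climate Data frame `date`, `ta_max`, `ta_min` for one site.
#' @param discharge Data frame `date`, `q` for the same days.
#' @param abc Numeric vector `c(a =, b =, c =)`, or a data frame of daily
#'   values with columns `a`, `b`, `c` (one row per day).
#' @param obs_sd Observation noise sd (degC), default 0.
#' @return Numeric vector of daily maximum water temperature.
#' @export
simulate_water_temperature <- function(climate, discharge, abc, obs_sd = 0) {
  n <- nrow(climate)
  if (is.data.frame(abc)) {
    a <- abc$a; b <- abc$b; cc <- abc$c
    if (length(a) != n) stopf("simulate_water_temperature: daily (a,b,c) must match the series length")
  } else {
    a <- rep(abc[["a"]], n); b <- rep(abc[["b"]], n); cc <- rep(abc[["c"]], n)
  }
  q <- discharge$q
  if (any(q <= 0)) stopf("simulate_water_temperature: discharge must be positive")
  gain <- abs(a + b) / q
  if (any(gain > 2))
    stopf("simulate_water_temperature: unstable configuration, |a+b|/Q = %.2f > 2 on day %d",
          max(gain), which.max(gain))
  tw <- numeric(n)
  tw[1] <- if (a[1] + b[1] > 0) {
    (a[1] * climate$ta_max[1] + b[1] * climate$ta_min[1] + cc[1] * q[1]) / (a[1] + b[1])
  } else climate$ta_max[1]
  for (t in seq_len(n - 1)) {
    tw[t + 1] <- tw[t] +
      (a[t] * (climate$ta_max[t] - tw[t]) + b[t] * (climate$ta_min[t] - tw[t])) / q[t] +
      cc[t]
  }
  if (obs_sd > 0) tw <- tw + stats::rnorm(n, 0, obs_sd)
  tw
}
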