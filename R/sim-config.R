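#' Configuration of a synthetic thermal study
#'
#' Bundles every knob of the synthetic-study generator with validation.
#' The defaults emulate the design of the regional study the analysis is
#' built for: 92 measurement sites observed daily over 2012-2018, with the
#' 17 regional summer extreme dates injected as heat waves.
#'
#' @param n_sites Number of measurement sites (>= 1).
#' @param start_year First simulated calendar year.
#' @param n_years Number of simulated years.
#' @param seed Integer seed; every stage derives its own stream from it.
#' @param latitude_deg Regional latitude (degrees north).
#' @param heat_wave_schedule Data frame with columns `date`, `amplitude`
#'   (degC added to air temperature at the peak) and `duration` (days); the
#'   default schedule places an 8 degC, 5-day triangular wave on each of the
#'   17 regional summer extreme dates.
#' @param coefficient_truth Per-response (`a`, `b`, `c`) lists of `intercept`
#'   and named `slopes` linking the standardised site covariates to the true
#'   thermal parameters.
#' @param coef_sd Named sd of the site-level noise added to `a`, `b`, `c`.
#' @param event_jitter_sd Named sd of per-event deviations of `(a, b, c)`
#'   inside event windows (0 = parameters constant per site, the default).
#' @param air_mean,air_amplitude Seasonal sinusoid of day maximum air
#'   temperature (degC): mean level and annual amplitude.
#' @param air_ar1_sd,air_ar1_phi Regional AR(1) air-temperature noise.
#' @param air_site_sd Per-site iid daily air-temperature noise (degC).
#' @param diurnal_range_mean,diurnal_range_sd Daily diurnal range (degC),
#'   `ta_min = ta_max - range`.
#' @param obs_sd Observation noise on water temperature (degC).
#' @param cellsize Raster cell size (m).
#' @param catchment_km2 Range of catchment areas (km2).
#' @param meander_amplitude,meander_period Meander sine amplitude and
#'   wavelength (m); amplitude 0 gives straight channels (sinuosity 1).
#' @param tree_density Riparian canopy density in `[0, 1]` (drives shade).
#' @param tree_height Canopy height (m) added to the surface model.
#' @param channel_gradient_range Range of per-catchment along-valley
#'   elevation gradients (m/m).
#' @param valley_cross_slope Cross-valley slope away from the channel (m/m).
#' @param base_elev_range Range of outlet elevations (m).
#' @param baseflow_range Range of per-site constant baseflow (flow units).
#' @param quickflow_share Mean quickflow volume as a share of baseflow
#'   volume (0 = groundwater-only flow, BFI 1).
#' @param storm_rate Storm arrival probability per day.
#' @param storm_decay Exponential recession rate of quickflow (1/day).
#' @param level_k_range Range of the per-site rating coefficient in
#'   `level = k * Q^0.4`.
#' @param sites_per_stem Sites nested on each stem (> 1 nests catchments).
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 92,
                       start_year = 2012,
                       n_years = 7,
                       seed = 1,
                       latitude_deg = 50,
                       heat_wave_schedule = NULL,
                       coefficient_truth = default_coefficient_truth(),
                       coef_sd = c(a = 0.2, b = 0.15, c = 0.03),
                       event_jitter_sd = c(a = 0, b = 0, c = 0),
                       air_mean = 10, air_amplitude = 9,
                       air_ar1_sd = 1.5, air_ar1_phi = 0.7,
                       air_site_sd = 0.3,
                       diurnal_range_mean = 8, diurnal_range_sd = 1.5,
                       obs_sd = 0.2,
                       cellsize = 20,
                       catchment_km2 = c(2, 8),
                       meander_amplitude = 60, meander_period = 800,
                       tree_density = 0.5, tree_height = 18,
                       channel_gradient_range = c(0.005, 0.03),
                       valley_cross_slope = 0.02,
                       base_elev_range = c(100, 400),
                       baseflow_range = c(3, 8),
                       quickflow_share = 0.5,
                       storm_rate = 0.08, storm_decay = 0.3,
                       level_k_range = c(0.15, 0.45),
                       sites_per_stem = 1) {
  start <- as.Date(sprintf("%d-01-01", start_year))
  end <- as.Date(sprintf("%d-12-31", start_year + n_years - 1))
  if (is.null(heat_wave_schedule)) {
    dts <- summer_extreme_dates()
    dts <- dts[dts >= start & dts <= end]
    heat_wave_schedule <- data.frame(date = dts, amplitude = 8, duration = 5)
  }
  heat_wave_schedule$date <- as_date(heat_wave_schedule$date)
  cfg <- list(
    n_sites = n_sites, start_year = start_year, n_years = n_years,
    start = start, end = end, seed = as.integer(seed),
    latitude_deg = latitude_deg,
    heat_wave_schedule = heat_wave_schedule,
    coefficient_truth = coefficient_truth,
    coef_sd = coef_sd, event_jitter_sd = event_jitter_sd,
    air_mean = air_mean, air_amplitude = air_amplitude,
    air_ar1_sd = air_ar1_sd, air_ar1_phi = air_ar1_phi,
    air_site_sd = air_site_sd,
    diurnal_range_mean = diurnal_range_mean, diurnal_range_sd = diurnal_range_sd,
    obs_sd = obs_sd,
    cellsize = cellsize, catchment_km2 = catchment_km2,
    meander_amplitude = meander_amplitude, meander_period = meander_period,
    tree_density = tree_density, tree_height = tree_height,
    channel_gradient_range = channel_gradient_range,
    valley_cross_slope = valley_cross_slope,
    base_elev_range = base_elev_range,
    baseflow_range = baseflow_range,
    quickflow_share = quickflow_share,
    storm_rate = storm_rate, storm_decay = storm_decay,
    level_k_range = level_k_range,
    sites_per_stem = sites_per_stem
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Default ground-truth links from covariates to the thermal parameters
#'
#' Day thermal sensitivity grows with watershed area and water level and
#' drops with shade; night sensitivity drops with the baseflow index
#' (groundwater buffering) and grows with open/disturbed cover; the
#' non-convective flux is small and weakly tied to land cover.  Slopes act
#' on standardised covariates.
#'
#' @return Named list of `intercept`/`slopes` per response.
#' @export
default_coefficient_truth <- function() {
  list(
    a = list(intercept = 2.0, slopes = c(AREA = 0.4, LEVEL = 0.3, SHADE = -0.3)),
    b = list(intercept = 1.2, slopes = c(BFI = -0.4, OTHER = 0.3, SINUO = -0.2)),
    c = list(intercept = 0.15, slopes = c(OTHER = 0.05, WATER = -0.03))
  )
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_sites)) stopf("sim_config: n_sites must be a positive integer")
  if (!is_count(cfg$n_years)) stopf("sim_config: n_years must be a positive integer")
  sds <- c(cfg$coef_sd, cfg$event_jitter_sd, cfg$air_ar1_sd, cfg$air_site_sd,
           cfg$diurnal_range_sd, cfg$obs_sd)
  if (any(sds < 0)) stopf("sim_config: all noise standard deviations must be >= 0")
  hw <- cfg$heat_wave_schedule
  if (nrow(hw) && (any(hw$date < cfg$start) || any(hw$date > cfg$end)))
    stopf("sim_config: heat-wave dates must fall inside the simulated period %s..%s",
          cfg$start, cfg$end)
  if (any(hw$duration < 1)) stopf("sim_config: heat-wave durations must be >= 1 day")
  if (cfg$cellsize <= 0) stopf("sim_config: cellsize must be positive")
  if (any(cfg$catchment_km2 <= 0) || diff(cfg$catchment_km2) < 0)
    stopf("sim_config: catchment_km2 must be a positive, non-decreasing range")
  if (cfg$tree_density < 0 || cfg$tree_density > 1)
    stopf("sim_config: tree_density must lie in [0, 1]")
  if (cfg$quickflow_share < 0) stopf("sim_config: quickflow_share must be >= 0")
  if (any(cfg$baseflow_range <= 0)) stopf("sim_config: baseflow must be positive")
  if (!is_count(cfg$sites_per_stem)) stopf("sim_config: sites_per_stem must be >= 1")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d sites, %d-%d, %d heat waves, seed %d\n",
              x$n_sites, x$start_year, x$start_year + x$n_years - 1,
              nrow(x$heat_wave_schedule), x$seed))
  invisible(x)
}
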