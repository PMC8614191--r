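#' Simulate a complete synthetic thermal study
#'
#' Orchestrates the generator: network and catchments, terrain and land
#' cover, climate with heat waves, discharge, then per-site true thermal
#' parameters and forward-simulated water temperature.  The true `(a, b, c)`
#' of each site are linear functions of its *computed* standardized
#' landscape covariates at the catchment (CA) scale (see
#' [default_coefficient_truth()]) plus Gaussian site noise, so the
#' downstream regression stage has a known ground truth; with all noise at
#' zero the full pipeline recovers the links exactly.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_study`: list with `config`, `network`, `dem`,
#'   `landcover`, `series` (named list of `daily_series`), `covariates`
#'   (per-site CA-scale landscape table), and `truth` (per-site true
#'   `(a, b, c)`, the standardized covariates, the injected extreme dates
#'   and per-site BFI).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ts_log("simulate_study: %d sites, seed %d", config$n_sites, config$seed)
  network <- generate_network(config)
  terrain <- generate_terrain_and_landcover(config, network)
  climate <- generate_climate(config, network)
  flow <- generate_discharge(config, network)

  # provisional series (water temperature filled after the truth is set)
  series <- list()
  for (sid in network$sites$site_id) {
    series[[sid]] <- data.frame(
      date = climate[[sid]]$date,
      ta_max = climate[[sid]]$ta_max, ta_min = climate[[sid]]$ta_min,
      tw_max = NA_real_, q = flow[[sid]]$q, level = flow[[sid]]$level)
  }

  event_dates <- config$heat_wave_schedule$date
  covariates <- assemble_landscape_table(
    terrain$dem, terrain$landcover, network, series,
    event_dates = event_dates, scales = "CA",
    water_buffer = max(2, config$cellsize / 2))

  # standardized covariates -> true (a, b, c); covariates that happen to be
  # constant across sites (possible in tiny configs) contribute nothing
  z <- covariates[, predictor_order()]
  for (cl in names(z)) {
    s <- stats::sd(z[[cl]])
    z[[cl]] <- if (!is.finite(s) || s == 0) rep(0, nrow(z)) else (z[[cl]] - mean(z[[cl]])) / s
  }
  set.seed(child_seed(config$seed, "coefficients"))
  truth_abc <- data.frame(site_id = covariates$site_id)
  for (resp in c("a", "b", "c")) {
    link <- config$coefficient_truth[[resp]]
    val <- rep(link$intercept, nrow(z))
    for (nm in names(link$slopes)) val <- val + link$slopes[[nm]] * z[[nm]]
    val <- val + stats::rnorm(nrow(z), 0, config$coef_sd[[resp]])
    if (resp %in% c("a", "b")) val <- pmax(val, 0.05)
    truth_abc[[resp]] <- val
  }

  # optional per-event jitter of the parameters inside event windows
  jitter_tab <- NULL
  if (any(config$event_jitter_sd > 0)) {
    jitter_tab <- expand.grid(site_id = truth_abc$site_id, date = event_dates,
                              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    for (resp in c("a", "b", "c")) {
      jitter_tab[[resp]] <- stats::rnorm(nrow(jitter_tab), 0,
                                         config$event_jitter_sd[[resp]])
    }
  }

  set.seed(child_seed(config$seed, "obsnoise"))
  for (i in seq_len(nrow(truth_abc))) {
    sid <- truth_abc$site_id[i]
    ser <- series[[sid]]
    abc <- daily_abc(truth_abc[i, ], jitter_tab, ser$date, event_dates)
    ser$tw_max <- simulate_water_temperature(ser, ser, abc, obs_sd = config$obs_sd)
    series[[sid]] <- validate_series(ser, sid)
  }

  structure(list(
    config = config, network = network,
    dem = terrain$dem, landcover = terrain$landcover,
    series = series, covariates = covariates,
    truth = list(abc = truth_abc, covariates_std = z,
                 event_jitter = jitter_tab,
                 extreme_dates = event_dates,
                 bfi = setNames(covariates$BFI, covariates$site_id))
  ), class = "synthetic_study")
}

# daily (a, b, c): site base values, replaced by base + per-event jitter on
# the 15-day windows around event dates
daily_abc <- function(base_row, jitter_tab, dates, event_dates) {
  n <- length(dates)
  out <- data.frame(a = rep(base_row$a, n), b = rep(base_row$b, n),
                    c = rep(base_row$c, n))
  if (is.null(jitter_tab)) return(out)
  jt <- jitter_tab[jitter_tab$site_id == base_row$site_id, , drop = FALSE]
  for (k in seq_len(nrow(jt))) {
    span <- which(abs(as.integer(dates - as.Date(jt$date[k]))) <= 7)
    out$a[span] <- base_row$a + jt$a[k]
    out$b[span] <- base_row$b + jt$b[k]
    out$c[span] <- base_row$c + jt$c[k]
  }
  out
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d sites, %s..%s, %d injected events\n",
              length(x$series), x$config$start, x$config$end,
              length(x$truth$extreme_dates)))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes `sites.csv`, `series/<site>.csv`, `dem.asc`, `landcover.asc`,
#' `network.geojson`, `catchments.geojson`, `events.csv` (the injected
#' schedule) and `truth.json` under `out_dir`.
#'
#' @param study A `synthetic_study`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_dataset <- function(study, out_dir) {
  dir.create(file.path(out_dir, "series"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$network$sites, file.path(out_dir, "sites.csv"),
                   row.names = FALSE, quote = FALSE)
  for (sid in names(study$series)) {
    write_series_csv(study$series[[sid]], file.path(out_dir, "series", paste0(sid, ".csv")))
  }
  write_esri_ascii(study$dem, file.path(out_dir, "dem.asc"))
  write_esri_ascii(study$landcover, file.path(out_dir, "landcover.asc"))
  write_network_geojson(study$network, file.path(out_dir, "network.geojson"))
  write_catchments_geojson(
    lapply(study$network$catchments, `[[`, "poly"),
    file.path(out_dir, "catchments.geojson"))
  write_events_csv(
    data.frame(date = study$truth$extreme_dates,
               season = assign_season(study$truth$extreme_dates)),
    file.path(out_dir, "events.csv"))
  truth <- list(
    abc = study$truth$abc,
    extreme_dates = format(study$truth$extreme_dates),
    bfi = as.list(study$truth$bfi),
    seed = study$config$seed)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(out_dir)
}

#' Generate and write a complete synthetic dataset
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return The `synthetic_study`, invisibly.
#' @export
make_dataset <- function(config, out_dir) {
  study <- simulate_study(config)
  write_dataset(study, out_dir)
  invisible(study)
}
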