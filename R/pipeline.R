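#' Run the full analysis pipeline
#'
#' Simulates (or ingests) a study, determines the extreme dates, fits the
#' thermal-dynamics model to every site x event window, aggregates the
#' summer values per site, computes the landscape table at the six spatial
#' scales, and runs the stepwise-AIC regressions per response and scale.
#'
#' @param config A [sim_config()] describing the synthetic study, or a
#'   `synthetic_study` already simulated.
#' @param events `"injected"` (default: use the generator's heat-wave
#'   schedule), `"detect"` (run [detect_extremes()]), or a data frame with
#'   a `date` column (bypass mode, externally supplied list).
#' @param scales Spatial scales to analyse (default all six).
#' @param mode Thermal fit mode (`"derivative"` or `"trajectory"`).
#' @param q,min_site_fraction Detection parameters when `events = "detect"`.
#' @param cast_shadows Passed to the shade computation.
#' @param out_dir Optional directory; when given, writes `events.csv`,
#'   `fits.csv`, `site_summer.csv`, `landscape.csv`, `report.csv` and the
#'   dataset itself.
#' @return List with `study`, `events`, `fits`, `site_summer`,
#'   `landscape`, `models` (list of `stepwise_report`) and `report`.
#' @export
run_pipeline <- function(config = sim_config(),
                         events = c("injected", "detect"),
                         scales = scale_names,
                         mode = "derivative",
                         q = 0.99, min_site_fraction = 0.5,
                         cast_shadows = TRUE,
                         out_dir = NULL) {
  study <- if (inherits(config, "synthetic_study")) config else simulate_study(config)
  cfg <- study$config

  if (is.data.frame(events)) {
    ev <- events
    ev$date <- as_date(ev$date)
    if (!"season" %in% names(ev)) ev$season <- assign_season(ev$date)
    ts_log("run_pipeline: %d externally supplied event(s)", nrow(ev))
  } else {
    events <- match.arg(events)
    ev <- if (events == "detect") {
      detect_extremes(study$series, q = q, min_site_fraction = min_site_fraction)
    } else {
      data.frame(date = study$truth$extreme_dates,
                 season = assign_season(study$truth$extreme_dates))
    }
  }
  summer_dates <- ev$date[ev$season == "summer"]

  fits <- fit_all_events(study$series, ev$date, mode = mode)
  ts_log("run_pipeline: %d thermal fits", nrow(fits))
  site_summer <- aggregate_summer(fits, study$series, summer_dates)

  landscape <- assemble_landscape_table(
    study$dem, study$landcover, study$network, study$series,
    event_dates = summer_dates, scales = scales,
    cast_shadows = cast_shadows,
    water_buffer = max(2, cfg$cellsize / 2))

  models <- list()
  for (sc in scales) {
    tab <- merge(site_summer[, c("site_id", "a", "b", "c")],
                 landscape[landscape$scale == sc, c("site_id", predictor_order())],
                 by = "site_id")
    complete <- stats::complete.cases(tab)
    if (any(!complete))
      ts_log("run_pipeline: scale %s drops %d incomplete row(s) (listwise)", sc, sum(!complete))
    tab <- tab[complete, , drop = FALSE]
    ztab <- standardize(tab, cols = predictor_order())
    for (resp in c("a", "b", "c")) {
      models[[paste(resp, sc, sep = ".")]] <-
        stepwise_aic(resp, data = ztab, scale_name = sc)
    }
  }
  report <- build_report(models)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dataset(study, out_dir)
    write_events_csv(ev, file.path(out_dir, "events.csv"))
    fits_out <- fits; fits_out$date <- format(fits_out$date)
    utils::write.csv(fits_out, file.path(out_dir, "fits.csv"), row.names = FALSE)
    utils::write.csv(site_summer, file.path(out_dir, "site_summer.csv"), row.names = FALSE)
    utils::write.csv(landscape, file.path(out_dir, "landscape.csv"), row.names = FALSE)
    utils::write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
  }

  list(study = study, events = ev, fits = fits, site_summer = site_summer,
       landscape = landscape, models = models, report = report)
}

#' Read the deposited per-scale analysis tables
#'
#' Adapter for the study's deposited per-scale CSVs (one file per spatial
#' scale, one row per site, standardized model and environmental
#' variables).  Columns are matched case-insensitively to the three model
#' variables (`a`, `b`, `c`) and the 15 predictor symbols of
#' [predictor_order()].
#'
#' @param dir Directory containing one CSV per scale; file names must
#'   contain the scale name (e.g. `CA`, `buff_1`, `ripa`).
#' @return Named list (by scale) of data frames.
#' @export
read_supplementary_tables <- function(dir) {
  if (!dir.exists(dir))
    stopf("supplementary data directory '%s' not found; download the study's per-scale CSVs there", dir)
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stopf("no CSVs found under '%s'", dir)
  out <- list()
  for (sc in scale_names) {
    pat <- paste0("(^|[^a-z0-9])", tolower(gsub("_", "[_.]?", sc)), "([^a-z0-9]|$)")
    hit <- files[grepl(pat, tolower(basename(files)))]
    # prefer the longest scale token match (buff_1_ripa over buff_1)
    if (sc %in% c("buff_1", "buff_2")) hit <- hit[!grepl("ripa", tolower(basename(hit)))]
    if (sc == "CA") hit <- hit[!grepl("ripa|buff", tolower(basename(hit)))]
    if (!length(hit)) stopf("no supplementary CSV found for scale '%s'", sc)
    df <- utils::read.csv(hit[1], stringsAsFactors = FALSE)
    names(df) <- toupper(names(df))
    want <- c(A = "a", B = "b", C = "c",
              setNames(predictor_order(), predictor_order()))
    missing_cols <- setdiff(names(want), names(df))
    if (length(missing_cols))
      stopf("supplementary table for scale '%s' lacks column(s): %s", sc,
            paste(missing_cols, collapse = ", "))
    sub <- df[, names(want)]
    names(sub) <- unname(want)
    out[[sc]] <- sub
  }
  out
}

#' Re-run the per-scale stepwise regressions on deposited tables
#'
#' @param tables Output of [read_supplementary_tables()].
#' @param responses Model variables to analyse.
#' @return List with `models`, `report`, `adj_r2` (percent, by
#'   response/scale) and `shade_forest_cor_CA` (Pearson correlation of
#'   SHADE with total forest cover BROAD + NEEDLE + FORESTS at CA scale).
#' @export
reproduce_scale_regressions <- function(tables, responses = c("a", "b", "c")) {
  models <- list()
  for (sc in names(tables)) {
    tab <- tables[[sc]][stats::complete.cases(tables[[sc]]), , drop = FALSE]
    ztab <- standardize(tab, cols = predictor_order())
    for (resp in responses) {
      models[[paste(resp, sc, sep = ".")]] <- stepwise_aic(resp, data = ztab,
                                                           scale_name = sc)
    }
  }
  ca <- tables[["CA"]]
  shade_forest <- if (!is.null(ca)) {
    stats::cor(ca$SHADE, ca$BROAD + ca$NEEDLE + ca$FORESTS,
               use = "complete.obs")
  } else NA_real_
  adj <- vapply(models, `[[`, 0, "adj_r2_pct")
  list(models = models, report = build_report(models),
       adj_r2 = adj, shade_forest_cor_CA = shade_forest)
}
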