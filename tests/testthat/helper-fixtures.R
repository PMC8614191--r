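# Shared fixtures, built in code.

options(thermosens.verbose = FALSE)

# A 15-day forcing window with water temperature generated by the forward
# daily model under known (a, b, c).
make_window <- function(a = 2, b = 1, cc = 0.1, q = 5, n = 15,
                        obs_sd = 0, seed = NULL, start = as.Date("2015-07-01"),
                        ta_wave = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  days <- seq_len(n)
  ta_max <- 24 + (if (ta_wave) 6 * exp(-((days - 8) / 2.5)^2) else 0) +
    stats::rnorm(n, 0, 1.2)
  rng <- pmax(3, 8 + stats::rnorm(n, 0, 1.5))
  df <- data.frame(date = start + days - 1,
                   ta_max = ta_max, ta_min = ta_max - rng,
                   tw_max = NA_real_, q = q, level = 0.4)
  df$tw_max <- simulate_water_temperature(df, df, c(a = a, b = b, c = cc),
                                          obs_sd = obs_sd)
  validate_series(df, "fixture")
}

fitted_window <- function(...) {
  s <- make_window(...)
  extract_window(s, s$date[8])
}

# A small synthetic study reused across test files (cached per session).
tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      hw <- data.frame(date = as.Date(c("2014-07-10", "2014-08-05", "2015-07-20")),
                       amplitude = 8, duration = 3)
      cfg <- sim_config(n_sites = 6, n_years = 2, start_year = 2014,
                        heat_wave_schedule = hw, catchment_km2 = c(1, 2),
                        cellsize = 25, seed = 42)
      cache <<- suppressWarnings(simulate_study(cfg))
    }
    cache
  }
})

# A hand-built two-reach network on a small template, for metric tests.
toy_network <- function(cell = 10, nr = 60, nc = 40) {
  tmpl <- raster_grid(matrix(NA_real_, nr, nc), cellsize = cell)
  # straight stem down the middle: from (200, 580) to (200, 20)
  stem <- cbind(rep(200, 57), seq(580, 20, by = -10))
  reaches <- list(
    R1 = list(id = "R1", to = "R2", da_km2 = 5, xy = stem[1:29, ]),
    R2 = list(id = "R2", to = NA_character_, da_km2 = 10, xy = stem[29:57, ])
  )
  sites <- data.frame(site_id = "S1", x = 200, y = 20, reach_id = "R2",
                      stem_id = "T", lat = 50, stringsAsFactors = FALSE)
  mask <- matrix(TRUE, nr, nc)
  structure(list(reaches = reaches, sites = sites,
                 catchments = list(S1 = list(rows = 1:nr, cols = 1:nc,
                                             mask = mask)),
                 template = tmpl),
            class = "river_network")
}
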