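test_that("meteorological seasons follow the month rule", {
  expect_equal(assign_season(as.Date("2012-08-19")), "summer")
  expect_equal(assign_season(as.Date("2014-06-09")), "summer")
  expect_equal(assign_season(as.Date("2014-12-15")), "winter")
  expect_equal(assign_season(as.Date("2015-03-01")), "spring")
  expect_equal(assign_season(as.Date("2015-11-30")), "autumn")
  # partition: every month maps to exactly one season
  months <- as.Date(sprintf("2014-%02d-15", 1:12))
  expect_true(all(assign_season(months) %in%
                    c("winter", "spring", "summer", "autumn")))
  expect_equal(unname(table(assign_season(months))[c("winter", "spring",
                                                     "summer", "autumn")]),
               rep(3L, 4), ignore_attr = TRUE)
})

sinus_series <- function(n_days = 730, noise_sd = 0, seed = 1,
                         start = as.Date("2014-01-01"), waves = NULL) {
  set.seed(seed)
  dates <- start + 0:(n_days - 1)
  doy <- as.integer(format(dates, "%j"))
  tw <- 12 + 7 * cos(2 * pi * (doy - 210) / 365.25) + rnorm(n_days, 0, noise_sd)
  if (!is.null(waves)) {
    for (d in as.list(waves)) {
      i <- which(dates == d)
      span <- (i - 1):(i + 1)
      tw[span] <- tw[span] + c(4, 8, 4)
    }
  }
  validate_series(data.frame(date = dates, ta_max = 20, ta_min = 10,
                             tw_max = tw, q = 5, level = 0.4), "sin")
}

test_that("the cyclic baseline absorbs a pure seasonal signal", {
  s <- sinus_series()
  bl <- fit_seasonal_baseline(s)
  expect_lt(max(abs(bl$residual)), 0.1)
  # constant series -> constant baseline
  sc <- s; sc$tw_max <- 9.5
  blc <- fit_seasonal_baseline(sc)
  expect_equal(unique(round(blc$baseline, 8)), 9.5)
  expect_error(fit_seasonal_baseline(s[1:200, ]), "full year")
})

test_that("baseline residuals reproduce the injected noise level", {
  s <- sinus_series(n_days = 1460, noise_sd = 0.8, seed = 3)
  bl <- fit_seasonal_baseline(s)
  expect_equal(sd(bl$residual), 0.8, tolerance = 0.15 * 0.8)
})

test_that("injected regional waves are detected at exactly their peak dates", {
  waves <- as.Date(c("2014-07-15", "2015-08-02", "2015-06-10"))
  series <- list(A = sinus_series(noise_sd = 0.5, seed = 4, waves = waves),
                 B = sinus_series(noise_sd = 0.5, seed = 5, waves = waves),
                 C = sinus_series(noise_sd = 0.5, seed = 6, waves = waves))
  ev <- detect_extremes(series, q = 0.99, min_site_fraction = 0.5)
  expect_setequal(format(ev$date), format(waves))
  expect_true(all(ev$fraction >= 0.5 & ev$fraction <= 1))
  expect_true(all(ev$season == "summer"))

  # no injected anomalies at a very high threshold -> empty
  clean <- list(A = sinus_series(noise_sd = 0, seed = 7))
  expect_equal(nrow(detect_extremes(clean, q = 0.995, min_site_fraction = 0.5)), 0)

  # monotonicity: f = 0 yields a superset of the f = 0.5 result
  ev0 <- detect_extremes(series, q = 0.99, min_site_fraction = 0)
  expect_true(all(ev$date %in% ev0$date))
  # raising q never adds extreme dates
  ev_hi <- detect_extremes(series, q = 0.997, min_site_fraction = 0.5)
  expect_true(all(ev_hi$date %in% ev$date))

  expect_error(detect_extremes(series, q = 0.4), "q must lie")
  expect_error(detect_extremes(series, q = 1), "q must lie")
})
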