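test_that("window extraction enforces margins and completeness", {
  s <- make_window(seed = 5, n = 15)
  w <- extract_window(s, s$date[8])
  expect_s3_class(w, "event_window")
  expect_equal(nrow(w), 15)
  expect_equal(as.data.frame(w), as.data.frame(s), ignore_attr = TRUE)

  expect_error(extract_window(s, s$date[3]), "margin")
  expect_error(extract_window(s, s$date[14]), "margin")

  s2 <- make_window(seed = 5, n = 31)
  s2$tw_max[10] <- NA
  expect_error(extract_window(s2, s2$date[16]), "missing")
})

test_that("the estimator exactly inverts the forward-Euler generator", {
  cases <- list(c(2, 1, 0.1), c(0.5, 0.2, -0.05), c(3.5, 0.01, 0.4))
  for (p in cases) {
    w <- fitted_window(a = p[1], b = p[2], cc = p[3], q = 5, obs_sd = 0, seed = 9)
    fit <- thermal_model(w)
    expect_equal(unname(coef(fit)), p, tolerance = 1e-9)
    expect_equal(fit$n_obs, 14)
    expect_lt(fit$rss, 1e-18)
  }
  # pure non-convective drift: a = b = 0, c = 0.3 -> +0.3 degC/day
  w <- fitted_window(a = 0, b = 0, cc = 0.3, obs_sd = 0, seed = 10)
  expect_equal(diff(w$tw_max), rep(0.3, 14), tolerance = 1e-12)
  fit <- thermal_model(w)
  expect_equal(unname(coef(fit)), c(0, 0, 0.3), tolerance = 1e-9)
})

test_that("water temperature converges to the fixed point under constant forcing", {
  n <- 200
  df <- data.frame(date = as.Date("2014-01-01") + 0:(n - 1),
                   ta_max = 25, ta_min = 15, tw_max = NA, q = 5, level = 0.4)
  a <- 1.2; b <- 0.7; cc <- 0.2
  tw <- simulate_water_temperature(df, df, c(a = a, b = b, c = cc))
  fp <- (a * 25 + b * 15 + cc * 5) / (a + b)
  expect_equal(tw[n], fp, tolerance = 1e-8)
  # a = b = c = 0 -> constant temperature
  tw0 <- simulate_water_temperature(df, df, c(a = 0, b = 0, c = 0))
  expect_equal(diff(range(tw0)), 0)
})

test_that("unstable daily stepping is rejected as a configuration error", {
  df <- data.frame(date = as.Date("2014-01-01") + 0:9,
                   ta_max = 25, ta_min = 15, tw_max = NA, q = 1, level = 0.4)
  expect_error(simulate_water_temperature(df, df, c(a = 1.5, b = 1, c = 0)),
               "unstable")
})

test_that("OLS equals the brute-force least-squares minimum on noisy windows", {
  set.seed(31)
  for (rep in 1:8) {
    w <- fitted_window(a = 2, b = 1, cc = 0.1, q = 5, obs_sd = 0.2)
    fit <- thermal_model(w)
    d <- diff(w$tw_max)
    x1 <- (w$ta_max[1:14] - w$tw_max[1:14]) / w$q[1:14]
    x2 <- (w$ta_min[1:14] - w$tw_max[1:14]) / w$q[1:14]
    # dense grid oracle over (a, b, c)
    grid <- as.matrix(expand.grid(a = seq(0.5, 3.5, length.out = 31),
                                  b = seq(-0.5, 2.5, length.out = 31),
                                  c = seq(-0.5, 0.7, length.out = 25)))
    pred <- grid %*% rbind(x1, x2, rep(1, 14))
    rss <- rowSums(sweep(pred, 2, d, `-`)^2)
    # the OLS solution beats every grid point, and the best grid point is
    # within the grid-resolution band of the optimum objective (the RSS
    # valley is flat along the correlated a-b direction, so coordinates of
    # the grid argmin are only loosely pinned)
    expect_lte(fit$rss, min(rss) + 1e-9)
    expect_lte(min(rss), fit$rss * 1.10 + 1e-6)
  }
})

test_that("rank-deficient windows raise a degenerate-fit error", {
  n <- 15
  df <- data.frame(date = as.Date("2014-01-01") + 0:(n - 1),
                   ta_max = 20, ta_min = 20, tw_max = 20, q = 5, level = 0.4)
  w <- extract_window(validate_series(df, "deg"), df$date[8])
  expect_error(thermal_model(w), "rank-deficient")
})

test_that("rescaling Q and (a, b) jointly leaves the trajectory invariant", {
  k <- 3.7
  w1 <- fitted_window(a = 2, b = 1, cc = 0.1, q = 5, obs_sd = 0, seed = 12)
  w2 <- as.data.frame(w1); w2$q <- w2$q * k
  w2$tw_max <- simulate_water_temperature(w2, w2, c(a = 2 * k, b = 1 * k, c = 0.1))
  expect_equal(w2$tw_max, w1$tw_max, tolerance = 1e-10)
  fit2 <- thermal_model(extract_window(validate_series(w2, "scaled"), w2$date[8]))
  expect_equal(unname(coef(fit2)), c(2 * k, 1 * k, 0.1), tolerance = 1e-8)
})

test_that("estimator error shrinks as observation noise shrinks", {
  errs <- vapply(c(0.4, 0.1, 0.01), function(sd) {
    set.seed(77)
    median(vapply(1:40, function(i) {
      w <- fitted_window(a = 2, b = 1, cc = 0.1, obs_sd = sd)
      abs(coef(thermal_model(w))[["a"]] - 2)
    }, 0))
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.02)
})

test_that("trajectory mode agrees with derivative mode on clean windows", {
  w <- fitted_window(a = 2, b = 1, cc = 0.1, obs_sd = 0, seed = 21)
  fd <- thermal_model(w, mode = "derivative")
  ft <- thermal_model(w, mode = "trajectory")
  expect_equal(coef(ft), coef(fd), tolerance = 1e-4)
})

test_that("thermal_fit methods behave like a fitted model object", {
  w <- fitted_window(a = 2, b = 1, cc = 0.1, obs_sd = 0.1, seed = 14)
  fit <- thermal_model(w)
  expect_output(print(fit), "day sensitivity")
  expect_output(print(summary(fit)), "Coefficients")
  expect_length(residuals(fit), 14)
  expect_equal(sum(residuals(fit)^2), fit$rss, tolerance = 1e-10)
  pr <- predict(fit)
  expect_length(pr, 15)
  expect_equal(pr[1], w$tw_max[1])
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(15L, 3L))
})

test_that("batch fitting logs skips and aggregates per site", {
  s1 <- make_window(seed = 1, n = 60, start = as.Date("2015-06-20"))
  s2 <- make_window(seed = 2, n = 60, start = as.Date("2015-06-20"))
  series <- list(A = s1, B = s2)
  dates <- as.Date(c("2015-07-01", "2015-07-20", "2015-06-21"))  # last lacks margin
  fits <- fit_all_events(series, dates)
  expect_equal(nrow(fits), 4)
  expect_equal(nrow(attr(fits, "skips")), 2)
  expect_equal(nrow(fit_all_events(series, as.Date(character(0)))), 0)

  agg <- aggregate_summer(fits, series, dates)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$a[agg$site_id == "A"],
               mean(fits$a[fits$site_id == "A"]))
  expect_equal(agg$n_events, c(2, 2))
  # identical values at all events -> the mean equals that value
  same <- fits; same$a <- 1.5
  agg2 <- aggregate_summer(same, series, dates)
  expect_equal(agg2$a, c(1.5, 1.5))
})
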