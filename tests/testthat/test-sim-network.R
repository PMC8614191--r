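test_that("zero meander amplitude gives sinuosity exactly 1 on every reach", {
  cfg <- sim_config(n_sites = 3, n_years = 1, start_year = 2014,
                    heat_wave_schedule = data.frame(date = as.Date("2014-07-10"),
                                                    amplitude = 8, duration = 3),
                    meander_amplitude = 0, catchment_km2 = c(1, 2),
                    cellsize = 25, seed = 2)
  net <- generate_network(cfg)
  stem_reaches <- Filter(function(r) grepl("_r", r$id), net$reaches)
  for (r in stem_reaches) expect_equal(reach_sinuosity(r$xy), 1, tolerance = 1e-12)
})

test_that("drainage area equals summed cell area and grows downstream", {
  cfg <- sim_config(n_sites = 4, n_years = 1, start_year = 2014,
                    heat_wave_schedule = data.frame(date = as.Date("2014-07-10"),
                                                    amplitude = 8, duration = 3),
                    catchment_km2 = c(1, 3), cellsize = 25, seed = 5)
  net <- generate_network(cfg)
  for (sid in net$sites$site_id) {
    info <- net$catchments[[sid]]
    da_cells <- sum(info$mask) * cfg$cellsize^2 / 1e6
    expect_equal(net$reaches[[net$sites$reach_id[net$sites$site_id == sid]]]$da_km2,
                 da_cells, tolerance = 1e-12)
  }
  # non-decreasing downstream along each stem chain
  for (r in net$reaches) {
    if (!is.na(r$to)) expect_lte(r$da_km2, net$reaches[[r$to]]$da_km2 + 1e-12)
  }
})

test_that("nested sites on one stem have nested catchment masks", {
  cfg <- sim_config(n_sites = 4, sites_per_stem = 2, n_years = 1,
                    start_year = 2014,
                    heat_wave_schedule = data.frame(date = as.Date("2014-07-10"),
                                                    amplitude = 8, duration = 3),
                    catchment_km2 = c(1, 2), cellsize = 25, seed = 8)
  net <- generate_network(cfg)
  expect_equal(nrow(net$sites), 4)
  by_stem <- split(net$sites$site_id, net$sites$stem_id)
  for (sids in by_stem) {
    expect_length(sids, 2)
    up <- net$catchments[[sids[1]]]; dn <- net$catchments[[sids[2]]]
    # same columns; upstream rows are a strict subset of downstream rows
    expect_identical(up$cols, dn$cols)
    expect_true(all(up$rows %in% dn$rows))
    expect_lt(length(up$rows), length(dn$rows))
  }
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_sites = 0), "n_sites")
  expect_error(sim_config(catchment_km2 = c(0, 1)), "catchment")
  expect_error(sim_config(obs_sd = -1), "standard deviations")
  expect_error(sim_config(heat_wave_schedule = data.frame(
    date = as.Date("2030-01-01"), amplitude = 8, duration = 3)),
    "inside the simulated period")
})

test_that("terrain decreases along the flow path and land cover uses the 8 codes", {
  # straight channels and no canopy give clean cell-centre sampling
  cfg <- sim_config(n_sites = 2, n_years = 1, start_year = 2014,
                    heat_wave_schedule = data.frame(date = as.Date("2014-07-10"),
                                                    amplitude = 8, duration = 3),
                    catchment_km2 = c(1, 1.5), cellsize = 25, seed = 6,
                    meander_amplitude = 0, tree_density = 0)
  net <- generate_network(cfg)
  ter <- generate_terrain_and_landcover(cfg, net)
  for (st in net$stems) {
    z <- vapply(seq_len(nrow(st$stem_xy)), function(i) {
      thermosens:::raster_value_at(ter$dem, st$stem_xy[i, 1], st$stem_xy[i, 2])
    }, 0)
    z <- z[!is.na(z)]
    expect_true(all(diff(z) <= 1e-9))
    expect_lt(z[length(z)], z[1])
  }
  codes <- unique(na.omit(as.vector(tiny_study()$landcover$values)))
  expect_true(all(codes %in% landcover_classes()))
})

test_that("a flat configuration yields zero channel slope and uniform shade", {
  cfg <- sim_config(n_sites = 2, n_years = 1, start_year = 2014,
                    heat_wave_schedule = data.frame(date = as.Date("2014-07-10"),
                                                    amplitude = 8, duration = 3),
                    catchment_km2 = c(1, 1.5), cellsize = 25, seed = 4,
                    channel_gradient_range = c(0, 0), valley_cross_slope = 0,
                    tree_density = 0)
  net <- generate_network(cfg)
  ter <- generate_terrain_and_landcover(cfg, net)
  expect_equal(suppressWarnings(channel_slope(ter$dem, net, "W001")), 0)
  # tree density 0 on flat terrain: median shade = 90 - sun elevation
  sun <- solar_position(as.Date("2014-07-10"), 50)
  info <- net$catchments[["W001"]]
  dem_loc <- thermosens:::crop_raster(ter$dem, info$rows, info$cols)
  water <- water_surface_mask(net, dem_loc, buffer_halfwidth = cfg$cellsize / 2)
  sh <- hillshade_angle(dem_loc, sun, cells = water & info$mask)
  med <- shade_metric(sh, water, info$mask)
  expect_equal(med, 90 - sun$elevation, tolerance = 1e-9)
})

test_that("raising riparian tree density raises the median shade on the water", {
  shades <- vapply(c(0, 0.4, 0.9), function(dens) {
    cfg <- sim_config(n_sites = 2, n_years = 1, start_year = 2014,
                      heat_wave_schedule = data.frame(date = as.Date("2014-07-10"),
                                                      amplitude = 8, duration = 3),
                      catchment_km2 = c(1, 1.5), cellsize = 25, seed = 31,
                      tree_density = dens)
    net <- generate_network(cfg)
    ter <- generate_terrain_and_landcover(cfg, net)
    sun <- solar_position(as.Date("2014-07-10"), 50)
    info <- net$catchments[["W001"]]
    dem_loc <- thermosens:::crop_raster(ter$dem, info$rows, info$cols)
    water <- water_surface_mask(net, dem_loc, buffer_halfwidth = cfg$cellsize / 2)
    sh <- hillshade_angle(dem_loc, sun, cells = water & info$mask)
    shade_metric(sh, water, info$mask)
  }, 0)
  expect_true(all(diff(shades) > 0))
})
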