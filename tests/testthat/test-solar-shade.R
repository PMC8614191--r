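test_that("solar-noon geometry matches standard solar tables", {
  # equinox at latitude 50N: declination ~ 0, noon elevation ~ 40 deg
  eq <- solar_position(as.Date("2013-03-20"), 50)
  expect_lt(abs(eq$declination), 0.6)
  expect_equal(eq$elevation, 40, tolerance = 0.5)
  expect_equal(eq$azimuth, 180)
  # summer solstice at 50N: noon elevation ~ 90 - 50 + 23.44
  sol <- solar_position(as.Date("2013-06-21"), 50)
  expect_equal(sol$elevation, 63.4, tolerance = 0.5)
  # winter solstice
  win <- solar_position(as.Date("2013-12-21"), 50)
  expect_equal(win$elevation, 16.6, tolerance = 0.5)
  expect_error(solar_position(as.Date("2013-06-21"), 70), "66.5")
})

flat_dem <- function(z = 100, n = 9, cell = 10) {
  raster_grid(matrix(z, n, n), cellsize = cell)
}

sun_at <- function(elev, az = 180) {
  list(date = as.Date("2015-07-01"), latitude = 50, declination = 0,
       elevation = elev, azimuth = az)
}

test_that("hillshade on flat terrain equals 90 minus sun elevation", {
  sh90 <- hillshade_angle(flat_dem(), sun_at(90))
  expect_equal(max(abs(sh90$values)), 0, tolerance = 1e-10)
  sh60 <- hillshade_angle(flat_dem(), sun_at(60))
  expect_equal(unique(round(as.vector(sh60$values), 10)), 30)
})

test_that("a 45-degree slope facing the sun at 45-degree elevation is fully lit", {
  # plane rising northward at 1 m per m -> south-facing 45 deg slope
  n <- 11; cell <- 5
  ys <- (n:1) * cell
  z <- matrix(rep(ys, each = n), n, n, byrow = TRUE)
  dem <- raster_grid(z, cellsize = cell)
  sh <- hillshade_angle(dem, sun_at(45), cast_shadows = FALSE)
  # interior cells (borders use clamped differences)
  expect_lt(max(abs(sh$values[3:(n - 2), 3:(n - 2)])), 1e-5)
  # independent 3-D vector-angle oracle: normal (0, -1, 1)/sqrt(2),
  # sun (0, -cos45, sin45): angle = acos(sqrt(2)/2 * (cos45 + sin45)) = 0
  oracle <- acos(min(1, sum(c(0, -1, 1) / sqrt(2) * c(0, -cos(pi / 4), sin(pi / 4)))))
  expect_lt(oracle, 1e-6)
})

test_that("cast shadows set occluded water cells to 90 degrees", {
  # flat plain with a 50 m wall across the south; sun low in the south
  n <- 21; cell <- 10
  z <- matrix(0, n, n)
  z[n - 1, ] <- 50           # wall one row north of the southern border
  dem <- raster_grid(z, cellsize = cell)
  cells <- matrix(FALSE, n, n); cells[n - 3, ] <- TRUE   # 20 m north of wall
  sun <- sun_at(20)           # horizon angle atan(50/20) = 68 deg > 20
  sh <- hillshade_angle(dem, sun, cells = cells, cast_shadows = TRUE)
  expect_true(all(sh$values[n - 3, ] == 90))
  sh_off <- hillshade_angle(dem, sun, cells = cells, cast_shadows = FALSE)
  expect_true(all(sh_off$values[n - 3, 5:15] < 90))
})

test_that("water-surface mask follows the drainage-area rules", {
  cell <- 1; nr <- 40; nc <- 21
  tmpl <- raster_grid(matrix(0, nr, nc), cellsize = cell)
  line <- cbind(rep(10, 2), c(38, 2))   # straight vertical reach at x = 10
  below <- list(list(id = "r", to = NA, da_km2 = 0.5, xy = line))
  expect_equal(sum(water_surface_mask(below, tmpl)), 0)

  small <- list(list(id = "r", to = NA, da_km2 = 10, xy = line))
  m <- water_surface_mask(small, tmpl)
  # geometric oracle: 2 m half-width corridor at 1 m cells -> centres at
  # |x - 10| <= 2, i.e. 4 columns (9.5, 10.5 at .5; 8.5, 11.5 at 1.5);
  # inner columns span 40 rows (rounded end caps reach dy = 1.93), outer
  # columns 38 rows (caps reach dy = 1.32): 2*40 + 2*38 = 156 cells
  hit_cols <- which(colSums(m) > 0)
  expect_equal(length(hit_cols), 4)
  expect_equal(sum(m), 156)

  big <- list(list(id = "r", to = NA, da_km2 = 100, xy = line))
  expect_gt(sum(water_surface_mask(big, tmpl)), sum(m))
})

test_that("shade metric is the median over water cells inside the footprint", {
  v <- matrix(NA_real_, 3, 3)
  v[1, 1:3] <- c(10, 20, 30)
  water <- matrix(FALSE, 3, 3); water[1, ] <- TRUE
  expect_equal(shade_metric(v, water, matrix(TRUE, 3, 3)), 20)
  # invariant to cells outside the water mask
  v2 <- v; v2[3, ] <- 85
  expect_equal(shade_metric(v2, water, matrix(TRUE, 3, 3)), 20)
  expect_warning(out <- shade_metric(v, water, matrix(FALSE, 3, 3)), "no water")
  expect_true(is.na(out))
  u <- matrix(25, 2, 2)
  expect_equal(shade_metric(u, matrix(TRUE, 2, 2), matrix(TRUE, 2, 2)), 25)
})
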