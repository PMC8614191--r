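#' Generate synthetic terrain and land cover
#'
#' Builds a surface model and a land-cover raster on the network template.
#' Elevation decreases monotonically along each channel (constant
#' along-valley gradient) and rises away from it (cross-valley slope);
#' riparian canopy cells within the 50 m corridor (but off the channel
#' itself) are raised by `tree_height` with probability `tree_density`,
#' emulating the vegetation signal a photogrammetric surface model carries.
#' Land cover uses the eight aggregated category codes of
#' [landcover_classes()]: each catchment receives Voronoi patches drawn from
#' a site-specific category mix, canopy cells are classed as broadleaved
#' forest and channel cells as water.
#'
#' @param config A [sim_config()].
#' @param network A `river_network` from [generate_network()].
#' @param seed Optional override of `config$seed`.
#' @return List with `dem` and `landcover` ([raster_grid]s on the network
#'   template; cells outside all catchments are no-data).
#' @export
generate_terrain_and_landcover <- function(config, network, seed = config$seed) {
  set.seed(child_seed(seed, "terrain"))
  tmpl <- network$template
  cs <- tmpl$cellsize
  dem <- matrix(NA_real_, nrow(tmpl$values), ncol(tmpl$values))
  lc <- matrix(NA_real_, nrow(tmpl$values), ncol(tmpl$values))
  classes <- landcover_classes()
  # mean patch mix; per-catchment gamma perturbation gives between-site
  # variation in cover proportions
  alpha <- c(HERBA = 2, BROAD = 2, NEEDLE = 1.5, AGRI = 2,
             WATER = 0.3, ARTI = 0.8, FORESTS = 1, OTHER = 0.8)

  for (st in network$stems) {
    rows <- (nrow(tmpl$values) - (st$y0 + st$h_m) / cs + 1):(nrow(tmpl$values) - st$y0 / cs)
    cols <- (st$x0 / cs + 1):(st$x0 / cs + st$w_c)
    rows <- as.integer(rows); cols <- as.integer(cols)
    local <- crop_raster(tmpl, rows, cols)
    cm <- raster_coord_matrices(local)
    # channel x-position at each cell's y
    x_stream <- st$xc + st$amp * sin(2 * pi * cm$y / config$meander_period + st$phase)
    elev <- st$base_elev +
      st$gradient * (cm$y - st$y0) +
      config$valley_cross_slope * abs(cm$x - x_stream)

    # channel cells: within half a cell of the stem line
    chan <- corridor_mask(local, st$stem_xy, max(2, cs / 2))
    # riparian canopy gallery on the west bank: at this resolution the
    # photogrammetric surface of a partly vegetated cell rises by the
    # canopy height times its fractional cover, so the band is raised by
    # tree_height * density.  A single-bank gallery keeps the
    # canopy-induced tilt of the water cells one-signed, so median shade
    # responds monotonically to the density dial (symmetric banks cancel
    # each other's Horn gradient at coarse cells).
    dens <- min(1, config$tree_density * stats::runif(1, 0.4, 1.6))
    rip <- (x_stream - cm$x) > 0 & (x_stream - cm$x) <= 50 & !chan
    elev[rip] <- elev[rip] + config$tree_height * dens
    canopy <- rip & matrix(stats::runif(length(elev)), nrow(elev)) < dens

    # land cover: Voronoi patches from a per-catchment category mix
    w <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    w <- w / sum(w)
    n_seeds <- 25L
    sx <- stats::runif(n_seeds, min(cm$x), max(cm$x))
    sy <- stats::runif(n_seeds, min(cm$y), max(cm$y))
    scat <- sample(classes, n_seeds, replace = TRUE, prob = w)
    d2min <- matrix(Inf, nrow(elev), ncol(elev))
    cat_here <- matrix(classes[[1]], nrow(elev), ncol(elev))
    for (k in seq_len(n_seeds)) {
      d2 <- (cm$x - sx[k])^2 + (cm$y - sy[k])^2
      upd <- d2 < d2min
      d2min[upd] <- d2[upd]
      cat_here[upd] <- scat[k]
    }
    cat_here[canopy] <- classes[["BROAD"]]
    cat_here[chan] <- classes[["WATER"]]

    dem[rows, cols] <- elev
    lc[rows, cols] <- cat_here
  }

  list(
    dem = raster_grid(dem, xll = tmpl$xll, yll = tmpl$yll, cellsize = cs),
    landcover = raster_grid(lc, xll = tmpl$xll, yll = tmpl$yll, cellsize = cs)
  )
}
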