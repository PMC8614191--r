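#' Generate a synthetic river network with sites and catchments
#'
#' Lays out one dendritic stem per catchment on a shared raster template
#' (catchments occupy disjoint rectangular tiles).  Each stem flows north to
#' south with a sinusoidal meander of configurable amplitude (amplitude 0
#' gives straight channels and sinuosity exactly 1), joined by two straight
#' tributaries, and is split into reaches at tributary junctions and site
#' outlets.  Per-reach drainage area grows downstream in proportion to the
#' upstream catchment cells, so the drainage area at a site outlet equals
#' the summed cell area of its catchment mask.  With `sites_per_stem > 1`,
#' sites are nested along the stem and upstream catchment masks are strict
#' subsets of downstream ones.
#'
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed`.
#' @return A `river_network`: list with `reaches` (named list of `id`, `to`,
#'   `da_km2`, `xy`), `sites` (data frame: `site_id`, `x`, `y`, `reach_id`,
#'   `stem_id`, `lat`), `catchments` (per site: `rows`, `cols`, `mask`,
#'   `poly`), `stems` (internal tile geometry) and `template` (global
#'   [raster_grid] filled with `NA`).
#' @export
generate_network <- function(config, seed = config$seed) {
  set.seed(child_seed(seed, "network"))
  cs <- config$cellsize
  n_stems <- ceiling(config$n_sites / config$sites_per_stem)

  # catchment areas and tile dimensions (aspect ~ 1:2, width:height)
  areas <- stats::runif(n_stems, config$catchment_km2[1], config$catchment_km2[2]) * 1e6
  w_m <- sqrt(areas / 2); h_m <- 2 * w_m
  w_c <- pmax(8L, as.integer(round(w_m / cs)))
  h_c <- pmax(16L, as.integer(round(h_m / cs)))
  if (any(w_c * h_c == 0)) stopf("generate_network: degenerate zero-area catchment")

  margin <- 2L
  slot_w <- max(w_c) + 2L * margin
  slot_h <- max(h_c) + 2L * margin
  n_col <- ceiling(sqrt(n_stems))
  n_row <- ceiling(n_stems / n_col)
  tmpl <- raster_grid(matrix(NA_real_, n_row * slot_h, n_col * slot_w),
                      xll = 0, yll = 0, cellsize = cs)

  reaches <- list(); stems <- list()
  sites <- data.frame(site_id = character(0), x = numeric(0), y = numeric(0),
                      reach_id = character(0), stem_id = character(0),
                      lat = numeric(0), stringsAsFactors = FALSE)
  catchments <- list()
  base_elev <- stats::runif(n_stems, config$base_elev_range[1], config$base_elev_range[2])
  gradients <- stats::runif(n_stems, config$channel_gradient_range[1],
                            config$channel_gradient_range[2])

  site_counter <- 0L
  for (s in seq_len(n_stems)) {
    grid_r <- (s - 1) %/% n_col; grid_c <- (s - 1) %% n_col
    # planar origin (lower-left) of this catchment rectangle
    x0 <- (grid_c * slot_w + margin) * cs
    y0 <- ((n_row - 1 - grid_r) * slot_h + margin) * cs
    wm <- w_c[s] * cs; hm <- h_c[s] * cs
    xc <- x0 + wm / 2
    phase <- stats::runif(1, 0, 2 * pi)

    # stem vertices from the top of the rectangle down to the outlet,
    # one vertex per cell row
    yy <- seq(y0 + hm, y0, by = -cs)
    amp <- min(config$meander_amplitude, wm / 2 - 2 * cs)
    amp <- max(amp, 0)
    xx <- xc + amp * sin(2 * pi * yy / config$meander_period + phase)
    stem_xy <- cbind(xx, yy)
    stem_id <- sprintf("S%03d", s)

    # breakpoints: tributary junctions at 40% / 70% down, site outlets at
    # evenly spaced fractions; vertices indexed from the top
    n_v <- nrow(stem_xy)
    n_here <- min(config$sites_per_stem, config$n_sites - site_counter)
    site_fracs <- seq_len(n_here) / n_here
    junc_fracs <- c(0.4, 0.7)
    brk <- sort(unique(c(
      pmax(2L, pmin(n_v, round(junc_fracs * (n_v - 1)) + 1L)),
      pmax(2L, pmin(n_v, round(site_fracs * (n_v - 1)) + 1L)),
      n_v
    )))
    total_cells <- w_c[s] * h_c[s]
    area_at <- function(v_idx) {
      # drainage area (km2) at stem vertex v_idx: full-width rows above it
      rows_above <- v_idx - 1L
      max(1L, rows_above * w_c[s]) * cs^2 / 1e6
    }

    prev_id <- NA_character_; start_v <- 1L
    seg_ids <- character(0)
    for (k in seq_along(brk)) {
      rid <- sprintf("%s_r%02d", stem_id, k)
      xy <- stem_xy[start_v:brk[k], , drop = FALSE]
      reaches[[rid]] <- list(id = rid, to = NA_character_, da_km2 = area_at(brk[k]),
                             xy = xy, stem_id = stem_id)
      if (!is.na(prev_id)) reaches[[prev_id]]$to <- rid
      prev_id <- rid; start_v <- brk[k]
      seg_ids <- c(seg_ids, rid)
    }
    # downstream links were set forward; the last reach keeps to = NA

    # two straight tributaries joining at the junction fractions
    junc_v <- pmax(2L, pmin(n_v, round(junc_fracs * (n_v - 1)) + 1L))
    for (t in seq_along(junc_v)) {
      jv <- junc_v[t]
      corner_x <- if (t == 1) x0 + 1.5 * cs else x0 + wm - 1.5 * cs
      top_y <- y0 + hm - 1.5 * cs
      trib_xy <- rbind(c(corner_x, top_y), stem_xy[jv, ])
      # the reach ending at this junction vertex
      ds <- seg_ids[which(brk == jv)[1] + 1L]
      if (is.na(ds)) ds <- seg_ids[length(seg_ids)]
      rid <- sprintf("%s_t%d", stem_id, t)
      reaches[[rid]] <- list(id = rid, to = ds,
                             da_km2 = 0.1 * total_cells * cs^2 / 1e6,
                             xy = trib_xy, stem_id = stem_id)
    }

    # sites at the site fractions; catchment mask = rectangle rows above
    for (j in seq_len(n_here)) {
      site_counter <- site_counter + 1L
      sid <- sprintf("W%03d", site_counter)
      v_idx <- pmax(2L, pmin(n_v, round(site_fracs[j] * (n_v - 1)) + 1L))
      pos <- stem_xy[v_idx, ]
      ds_reach <- seg_ids[which(brk == v_idx)[1]]
      sites <- rbind(sites, data.frame(
        site_id = sid, x = unname(pos[1]), y = unname(pos[2]), reach_id = ds_reach,
        stem_id = stem_id, lat = config$latitude_deg, stringsAsFactors = FALSE))
      # global row/col window of the catchment (rows above the outlet vertex)
      top_row <- nrow(tmpl$values) - (y0 + hm) / cs + 1L
      out_row <- nrow(tmpl$values) - floor(pos[2] / cs)
      left_col <- x0 / cs + 1L
      rows <- as.integer(top_row):as.integer(min(out_row, top_row + h_c[s] - 1L))
      cols <- as.integer(left_col):as.integer(left_col + w_c[s] - 1L)
      mask <- matrix(TRUE, length(rows), length(cols))
      y_bot <- y0 + hm - length(rows) * cs
      poly <- rbind(c(x0, y_bot), c(x0 + wm, y_bot),
                    c(x0 + wm, y0 + hm), c(x0, y0 + hm), c(x0, y_bot))
      catchments[[sid]] <- list(rows = rows, cols = cols, mask = mask, poly = poly)
      # exact drainage area from the mask
      da <- length(rows) * length(cols) * cs^2 / 1e6
      reaches[[ds_reach]]$da_km2 <- max(reaches[[ds_reach]]$da_km2, da)
    }

    stems[[stem_id]] <- list(id = stem_id, x0 = x0, y0 = y0, w_m = wm, h_m = hm,
                             w_c = w_c[s], h_c = h_c[s], xc = xc, amp = amp,
                             phase = phase, base_elev = base_elev[s],
                             gradient = gradients[s],
                             stem_xy = stem_xy)
  }

  # enforce non-decreasing drainage area downstream along every stem
  for (st in stems) {
    ids <- names(reaches)[vapply(reaches, function(r) identical(r$stem_id, st$id) &&
                                   grepl("_r", r$id), TRUE)]
    running <- 0
    for (rid in ids) {
      running <- max(running, reaches[[rid]]$da_km2)
      reaches[[rid]]$da_km2 <- running
    }
  }

  structure(list(reaches = reaches, sites = sites, catchments = catchments,
                 stems = stems, template = tmpl),
            class = "river_network")
}

#' @export
print.river_network <- function(x, ...) {
  cat(sprintf("river_network: %d reaches, %d sites, template %d x %d cells (%g m)\n",
              length(x$reaches), nrow(x$sites),
              nrow(x$template$values), ncol(x$template$values), x$template$cellsize))
  invisible(x)
}

# crop the global template/raster to a site's catchment window
crop_raster <- function(g, rows, cols) {
  sub <- g$values[rows, cols, drop = FALSE]
  raster_grid(sub,
              xll = g$xll + (min(cols) - 1) * g$cellsize,
              yll = g$yll + (nrow(g$values) - max(rows)) * g$cellsize,
              cellsize = g$cellsize, nodata = g$nodata)
}
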