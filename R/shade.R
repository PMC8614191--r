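# Shade on the water surface: solar-incidence hillshading of a surface model
# (terrain + canopy), optionally with cast shadows, masked to the mapped
# water surface and summarised by the median within each spatial footprint.

# edge-clamped shift of a matrix by (dr, dc)
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

#' Solar-incidence shade angles from a surface model
#'
#' For each cell, the angle between the surface normal (from Horn
#' 8-neighbour finite-difference gradients; borders use edge-clamped
#' differences) and the direction of the sun, clamped to `[0, 90]` degrees:
#' 0 = surface faces the sun squarely, 90 = grazing or self-shadowed.  With
#' `cast_shadows = TRUE` (the default) a ray is marched from each evaluated
#' cell along the sun azimuth; where the local horizon angle exceeds the sun
#' elevation the cell lies in a cast shadow and its shade is set to 90.
#'
#' @param dem A [raster_grid] surface model (terrain plus canopy), >= 3x3.
#' @param sun A [solar_position()] result.
#' @param cells Optional logical matrix (dim of `dem`): evaluate shade only
#'   where `TRUE` (e.g. on water-surface cells); other cells return `NA`.
#' @param cast_shadows March rays toward the sun to detect occlusion.
#' @param max_shadow_dist Maximum ray length in metres (default 300).
#' @return A [raster_grid] of shade angles in degrees.
#' @export
hillshade_angle <- function(dem, sun, cells = NULL, cast_shadows = TRUE,
                            max_shadow_dist = 300) {
  stopifnot(inherits(dem, "raster_grid"))
  z <- dem$values
  if (nrow(z) < 3 || ncol(z) < 3) stopf("hillshade_angle: DEM must be at least 3x3")
  cs <- dem$cellsize
  # Horn gradients (x = east, y = north; row 1 is the northern edge)
  p <- (shift_mat(z, -1, 1) + 2 * shift_mat(z, 0, 1) + shift_mat(z, 1, 1) -
        shift_mat(z, -1, -1) - 2 * shift_mat(z, 0, -1) - shift_mat(z, 1, -1)) / (8 * cs)
  qg <- (shift_mat(z, -1, -1) + 2 * shift_mat(z, -1, 0) + shift_mat(z, -1, 1) -
         shift_mat(z, 1, -1) - 2 * shift_mat(z, 1, 0) - shift_mat(z, 1, 1)) / (8 * cs)
  az <- sun$azimuth * pi / 180
  el <- sun$elevation * pi / 180
  sx <- sin(az) * cos(el); sy <- cos(az) * cos(el); sz <- sin(el)
  cosang <- (-p * sx - qg * sy + sz) / sqrt(1 + p^2 + qg^2)
  ang <- acos(pmax(pmin(cosang, 1), -1)) * 180 / pi
  shade <- pmin(ang, 90)

  eval_mask <- if (is.null(cells)) matrix(TRUE, nrow(z), ncol(z)) else cells
  if (cast_shadows && any(eval_mask)) {
    idx <- which(eval_mask)
    rr <- ((idx - 1) %% nrow(z)) + 1
    cc <- ((idx - 1) %/% nrow(z)) + 1
    z0 <- z[idx]
    horizon <- rep(-Inf, length(idx))
    n_steps <- max(1L, floor(max_shadow_dist / cs))
    dx <- sin(az); dy <- cos(az)       # horizontal unit vector toward the sun
    for (s in seq_len(n_steps)) {
      d <- s * cs
      cj <- round(cc + dx * d / cs)
      ri <- round(rr - dy * d / cs)    # northward = decreasing row
      ok <- ri >= 1 & ri <= nrow(z) & cj >= 1 & cj <= ncol(z)
      if (!any(ok)) break
      zi <- rep(NA_real_, length(idx))
      zi[ok] <- z[cbind(ri[ok], cj[ok])]
      horizon <- pmax(horizon, atan((zi - z0) / d), na.rm = TRUE)
    }
    shadowed <- horizon > el
    shade[idx[shadowed]] <- 90
  }
  if (!is.null(cells)) shade[!cells] <- NA_real_
  raster_grid(shade, xll = dem$xll, yll = dem$yll, cellsize = cs, nodata = dem$nodata)
}

# half-width (m) of the water surface for a reach of drainage area da (km2):
# mapped surfaces above the threshold widen with drainage area; smaller
# mapped reaches use the fixed 2 m line buffer.
water_halfwidth <- function(da_km2, mapped_threshold = 50, buffer_halfwidth = 2) {
  ifelse(da_km2 >= mapped_threshold,
         pmax(buffer_halfwidth, 0.6 * sqrt(da_km2)),
         buffer_halfwidth)
}

#' Rasterise the water surface of a river network
#'
#' Reaches with drainage area of at least `mapped_threshold` km2 contribute
#' their mapped water surface (a corridor whose half-width grows with
#' drainage area); reaches between `min_da` and the threshold contribute a
#' fixed `buffer_halfwidth` (2 m) corridor around the network line; reaches
#' below `min_da` (1 km2) are excluded.
#'
#' @param network `river_network` or a plain reach list.
#' @param template [raster_grid] defining the output geometry.
#' @param min_da Minimum drainage area (km2) for a reach to count as water.
#' @param mapped_threshold Drainage area (km2) above which the mapped water
#'   surface replaces the fixed line buffer.
#' @param buffer_halfwidth Fixed half-width (m) for small mapped reaches.
#' @return Logical matrix (dim of `template`), `TRUE` on water cells.
#' @export
water_surface_mask <- function(network, template, min_da = 1,
                               mapped_threshold = 50, buffer_halfwidth = 2) {
  reaches <- if (inherits(network, "river_network")) network$reaches else network
  mask <- matrix(FALSE, nrow(template$values), ncol(template$values))
  for (r in reaches) {
    if (r$da_km2 < min_da) next
    hw <- water_halfwidth(r$da_km2, mapped_threshold, buffer_halfwidth)
    mask <- mask | corridor_mask(template, r$xy, hw)
  }
  mask
}

#' Median shade over the water surface of a footprint
#'
#' @param shade [raster_grid] (or matrix) of shade angles.
#' @param water_mask Logical matrix of water-surface cells.
#' @param scale_mask Logical matrix of the spatial-scale footprint.
#' @return Median shade angle in degrees, or `NA` (with a warning) when the
#'   footprint contains no water cells.
#' @export
shade_metric <- function(shade, water_mask, scale_mask) {
  v <- if (inherits(shade, "raster_grid")) shade$values else shade
  sel <- water_mask & scale_mask
  vals <- v[sel]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) {
    warnf("shade_metric: footprint contains no water-surface cells")
    return(NA_real_)
  }
  stats::median(vals)
}
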