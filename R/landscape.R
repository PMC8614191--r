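#' Assemble the environmental-variable table per site and spatial scale
#'
#' Computes the 15 environmental variables for each site at each requested
#' spatial scale:
#' \itemize{
#'   \item \strong{SHADE}: per event date, the median solar-incidence shade
#'     angle over water-surface cells in the footprint, averaged over the
#'     event dates.  Computed on the watercourse, so identical within the
#'     CA/ripa, buff_1/buff_1_ripa and buff_2/buff_2_ripa pairs.
#'   \item \strong{SINUO}: length-weighted upstream reach sinuosity
#'     (same pairing as SHADE).
#'   \item \strong{AGRI, ARTI, BROAD, HERBA, FORESTS, NEEDLE, OTHER,
#'     WATER}: land-cover percentages within the footprint.
#'   \item \strong{AREA, SLOP, ELEV, BFI, LEVEL}: station-scale variables
#'     (watershed area, channel slope over ~4 km, site elevation, baseflow
#'     index, mean water level at the event dates), replicated across
#'     scales.
#' }
#'
#' @param dem,landcover Global [raster_grid]s.
#' @param network `river_network` with per-site catchments.
#' @param series_list Named list of `daily_series` (discharge for BFI,
#'   level for LEVEL).
#' @param event_dates Dates over which SHADE and LEVEL are averaged.
#' @param scales Subset of the six scale names (default all).
#' @param radii Buffer radii (m).
#' @param corridor Riparian corridor half-width per side (m).
#' @param slope_distance Channel distance for SLOP (m).
#' @param cast_shadows Passed to [hillshade_angle()].
#' @param water_buffer Half-width (m) of the line buffer used to rasterise
#'   the water surface of unmapped reaches; defaults to
#'   `max(2, cellsize / 2)` so the channel line is resolved at the working
#'   resolution.
#' @return Data frame: `site_id`, `scale`, then the 15 variables.
#' @export
assemble_landscape_table <- function(dem, landcover, network, series_list,
                                     event_dates,
                                     scales = scale_names,
                                     radii = c(1000, 2000), corridor = 50,
                                     slope_distance = 4000,
                                     cast_shadows = TRUE,
                                     water_buffer = NULL) {
  event_dates <- as_date(event_dates)
  scales <- match.arg(scales, scale_names, several.ok = TRUE)
  if (is.null(water_buffer)) water_buffer <- max(2, dem$cellsize / 2)
  suns <- lapply(event_dates, solar_position,
                 latitude_deg = network$sites$lat[1])
  lc_classes <- landcover_classes()
  rows <- list()
  for (si in seq_len(nrow(network$sites))) {
    sid <- network$sites$site_id[si]
    cat_info <- network$catchments[[sid]]
    dem_loc <- crop_raster(dem, cat_info$rows, cat_info$cols)
    lc_loc <- crop_raster(landcover, cat_info$rows, cat_info$cols)
    masks <- build_scale_masks(cat_info$mask, network, sid, dem_loc,
                               radii = radii, corridor = corridor)
    water <- water_surface_mask(network, dem_loc, buffer_halfwidth = water_buffer)
    water <- water & cat_info$mask

    # shade per pair scale, averaged over event dates
    pair_scales <- unique(scale_pair[scales])
    shade_by_pair <- setNames(rep(0, length(pair_scales)), pair_scales)
    n_ok <- setNames(rep(0L, length(pair_scales)), pair_scales)
    for (sun in suns) {
      sh <- hillshade_angle(dem_loc, sun, cells = water,
                            cast_shadows = cast_shadows)
      for (ps in pair_scales) {
        v <- shade_metric(sh, water, masks[[ps]])
        if (!is.na(v)) {
          shade_by_pair[ps] <- shade_by_pair[ps] + v
          n_ok[ps] <- n_ok[ps] + 1L
        }
      }
    }
    shade_by_pair <- ifelse(n_ok > 0, shade_by_pair / n_ok, NA_real_)

    sinuo_by_pair <- vapply(pair_scales, function(ps) {
      tryCatch(network_sinuosity(network, sid, masks[[ps]], dem_loc),
               error = function(e) NA_real_)
    }, 0)

    ser <- series_list[[sid]]
    bfi <- tryCatch(compute_bfi(ser$q[!is.na(ser$q)]), error = function(e) NA_real_)
    lev <- mean(ser$level[ser$date %in% event_dates], na.rm = TRUE)
    area <- sum(cat_info$mask) * dem$cellsize^2 / 1e6
    slop <- tryCatch(channel_slope(dem, network, sid, slope_distance),
                     error = function(e) NA_real_)
    elev <- tryCatch(site_elevation(dem, network, sid), error = function(e) NA_real_)

    for (sc in scales) {
      props <- tryCatch(landcover_proportions(lc_loc, masks[[sc]], lc_classes),
                        error = function(e) {
                          warnf("site %s scale %s: %s", sid, sc, conditionMessage(e))
                          setNames(rep(NA_real_, length(lc_classes)), names(lc_classes))
                        })
      rows[[length(rows) + 1]] <- data.frame(
        site_id = sid, scale = sc,
        SHADE = shade_by_pair[[scale_pair[[sc]]]],
        SINUO = sinuo_by_pair[[scale_pair[[sc]]]],
        AGRI = props[["AGRI"]], ARTI = props[["ARTI"]], BROAD = props[["BROAD"]],
        HERBA = props[["HERBA"]], FORESTS = props[["FORESTS"]],
        NEEDLE = props[["NEEDLE"]], OTHER = props[["OTHER"]],
        WATER = props[["WATER"]],
        AREA = area, SLOP = slop, LEVEL = lev, ELEV = elev, BFI = bfi,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_missing <- sum(!stats::complete.cases(out))
  if (n_missing) ts_log("assemble_landscape_table: %d row(s) carry missing metrics", n_missing)
  out
}
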