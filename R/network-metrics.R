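# Stream network-dependent metrics: reach sinuosity (weighted by upstream
# reach length) and the local channel slope over ~4 km of channel.

# ids of all reaches whose flow passes through reach `rid` (including rid)
upstream_reach_ids <- function(reaches, rid) {
  ids <- names(reaches)
  downstream_of <- vapply(reaches, function(r) r$to %||% NA_character_, "")
  keep <- character(0)
  frontier <- rid
  while (length(frontier)) {
    keep <- c(keep, frontier)
    frontier <- ids[!is.na(downstream_of) & downstream_of %in% frontier & !(ids %in% keep)]
  }
  keep
}

#' Sinuosity of one reach
#'
#' Channel length divided by the straight-line distance between the reach
#' endpoints (the "mean axis").  1 = straight, larger = meandering.
#'
#' @param xy Two-column vertex matrix, upstream to downstream.
#' @return Sinuosity (>= 1 up to floating point).
#' @export
reach_sinuosity <- function(xy) {
  straight <- sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
  if (straight == 0) stopf("reach_sinuosity: zero straight-line distance (closed loop)")
  polyline_length(xy) / straight
}

#' Length-weighted sinuosity of the upstream network
#'
#' Per-reach sinuosities of all reaches upstream of the site, weighted by
#' reach channel length; optionally restricted to reaches intersecting a
#' spatial-scale footprint.
#'
#' @param network `river_network`.
#' @param site_id Site identifier (a row of `network$sites`).
#' @param scale_mask Optional logical footprint matrix on `template`.
#' @param template [raster_grid] used to interpret `scale_mask`.
#' @return Weighted mean sinuosity.
#' @export
network_sinuosity <- function(network, site_id, scale_mask = NULL, template = NULL) {
  site <- network$sites[network$sites$site_id == site_id, ]
  if (nrow(site) != 1) stopf("network_sinuosity: unknown site '%s'", site_id)
  ids <- upstream_reach_ids(network$reaches, site$reach_id)
  lens <- numeric(0); sinu <- numeric(0)
  for (rid in ids) {
    r <- network$reaches[[rid]]
    if (!is.null(scale_mask)) {
      idx <- raster_cell_index(template, r$xy[, 1], r$xy[, 2])
      ok <- !is.na(idx[, 1])
      if (!any(ok) || !any(scale_mask[idx[ok, , drop = FALSE]])) next
    }
    lens <- c(lens, polyline_length(r$xy))
    sinu <- c(sinu, reach_sinuosity(r$xy))
  }
  if (!length(lens)) stopf("network_sinuosity: no upstream reach intersects the footprint for site '%s'", site_id)
  sum(lens * sinu) / sum(lens)
}

# walk upstream from the site outlet along the main stem (largest drainage
# area at each confluence); returns the traversed vertex matrix
upstream_channel_path <- function(network, site_id, distance) {
  site <- network$sites[network$sites$site_id == site_id, ]
  if (nrow(site) != 1) stopf("channel path: site '%s' not on network", site_id)
  r <- network$reaches[[site$reach_id]]
  if (is.null(r)) stopf("channel path: site '%s' references unknown reach", site_id)
  # start at the reach vertex closest to the site outlet
  d2 <- (r$xy[, 1] - site$x)^2 + (r$xy[, 2] - site$y)^2
  cut <- which.min(d2)
  path <- r$xy[seq_len(cut), , drop = FALSE]
  walked <- polyline_length(path)
  current <- r$id
  while (walked < distance) {
    parents <- Filter(function(p) identical(p$to, current), network$reaches)
    if (!length(parents)) break
    main <- parents[[which.max(vapply(parents, `[[`, 0, "da_km2"))]]
    path <- rbind(main$xy, path)
    walked <- walked + polyline_length(main$xy)
    current <- main$id
  }
  # trim from the upstream end to the requested channel distance
  if (walked > distance) {
    seg <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
    cum_from_outlet <- rev(cumsum(rev(seg)))
    keep <- which(cum_from_outlet <= distance)
    if (length(keep)) {
      first <- keep[1]
      # interpolate the exact upstream point on the segment entering `first`
      over <- cum_from_outlet[first]
      if (first > 1 && over < distance) {
        f <- (distance - over) / seg[first - 1]
        newpt <- path[first, ] + f * (path[first - 1, ] - path[first, ])
        path <- rbind(newpt, path[first:nrow(path), , drop = FALSE])
      } else {
        path <- path[first:nrow(path), , drop = FALSE]
      }
    }
  } else if (walked < distance) {
    warnf("channel slope for site '%s': only %.0f m of channel upstream (requested %.0f m)",
          site_id, walked, distance)
  }
  path
}

#' Local channel slope at a site
#'
#' Elevation difference between a point `distance` metres upstream along the
#' channel (main stem at confluences) and the site outlet, divided by the
#' channel length between them, in percent.  Truncated with a warning when
#' less channel is available.
#'
#' @param dem [raster_grid] elevation model.
#' @param network `river_network`.
#' @param site_id Site identifier.
#' @param distance Channel distance in metres (default 4000).
#' @return Slope in percent.
#' @export
channel_slope <- function(dem, network, site_id, distance = 4000) {
  path <- upstream_channel_path(network, site_id, distance)
  len <- polyline_length(path)
  if (len <= 0) stopf("channel_slope: degenerate channel path for site '%s'", site_id)
  elev_up <- raster_value_at(dem, path[1, 1], path[1, 2])
  elev_dn <- raster_value_at(dem, path[nrow(path), 1], path[nrow(path), 2])
  if (is.na(elev_up) || is.na(elev_dn))
    stopf("channel_slope: channel path leaves the DEM for site '%s'", site_id)
  100 * (elev_up - elev_dn) / len
}

#' Elevation at the measurement site
#'
#' @param dem [raster_grid].
#' @param network `river_network`.
#' @param site_id Site identifier.
#' @return DEM value at the site cell (m).
#' @export
site_elevation <- function(dem, network, site_id) {
  site <- network$sites[network$sites$site_id == site_id, ]
  v <- raster_value_at(dem, site$x, site$y)
  if (is.na(v)) stopf("site_elevation: site '%s' outside the DEM", site_id)
  v
}
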