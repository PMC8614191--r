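# Vector I/O: the river network and catchment outlines travel as GeoJSON
# FeatureCollections in planar metric coordinates.  Reaches are LineString
# features ordered upstream -> downstream with properties `reach_id`,
# `ds_id` (downstream reach id, NA at the outlet) and `da_km2` (drainage
# area).  Catchments are Polygon features with property `site_id`.

#' Write a river network to GeoJSON
#'
#' @param network A `river_network` (see [generate_network()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_network_geojson <- function(network, path) {
  feats <- lapply(network$reaches, function(r) {
    props <- list(reach_id = r$id, da_km2 = r$da_km2)
    if (!is.na(r$to)) props$ds_id <- r$to
    list(
      type = "Feature",
      properties = props,
      geometry = list(type = "LineString",
                      coordinates = unname(apply(r$xy, 1, c, simplify = FALSE)))
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a river network from GeoJSON
#'
#' Validates that every reach carries `reach_id` and `da_km2` properties and
#' a LineString geometry.
#'
#' @param path Path to a GeoJSON FeatureCollection of reaches.
#' @return A list of reaches (`id`, `to`, `da_km2`, `xy`), class
#'   `river_network` once site information is attached by the caller.
#' @export
read_network_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) stopf("%s is not a FeatureCollection", path)
  reaches <- lapply(fc$features, function(f) {
    p <- f$properties
    if (is.null(p$reach_id)) stopf("reach feature missing required property 'reach_id'")
    if (is.null(p$da_km2))
      stopf("reach '%s' missing required property 'da_km2'", p$reach_id)
    if (!identical(f$geometry$type, "LineString"))
      stopf("reach '%s' geometry must be LineString", p$reach_id)
    xy <- do.call(rbind, lapply(f$geometry$coordinates, function(v) unlist(v)[1:2]))
    list(id = as.character(p$reach_id),
         to = if (is.null(p$ds_id)) NA_character_ else as.character(p$ds_id),
         da_km2 = as.numeric(p$da_km2),
         xy = xy)
  })
  names(reaches) <- vapply(reaches, `[[`, "", "id")
  reaches
}

#' Write catchment outlines to GeoJSON
#'
#' @param catchments Named list (by site id) of two-column vertex matrices.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_catchments_geojson <- function(catchments, path) {
  feats <- lapply(names(catchments), function(sid) {
    poly <- catchments[[sid]]
    if (!all(poly[1, ] == poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
    list(
      type = "Feature",
      properties = list(site_id = sid),
      geometry = list(type = "Polygon",
                      coordinates = list(unname(apply(poly, 1, c, simplify = FALSE))))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read catchment outlines from GeoJSON
#'
#' @param path Path to a GeoJSON FeatureCollection of catchment polygons.
#' @return Named list (by `site_id`) of two-column vertex matrices.
#' @export
read_catchments_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) stopf("%s is not a FeatureCollection", path)
  out <- list()
  for (f in fc$features) {
    sid <- f$properties$site_id
    if (is.null(sid)) stopf("catchment feature missing required property 'site_id'")
    ring <- f$geometry$coordinates[[1]]
    out[[as.character(sid)]] <- do.call(rbind, lapply(ring, function(v) unlist(v)[1:2]))
  }
  out
}
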