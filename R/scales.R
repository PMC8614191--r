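# The six spatial scales used to aggregate environmental variables:
#   CA           entire upstream catchment
#   buff_1/2     part of the 1 km / 2 km disc around the site inside CA
#   ripa         50 m corridor on each side of the upstream network, in CA
#   buff_k_ripa  ripa restricted to the k-km disc
scale_names <- c("CA", "buff_1", "buff_2", "ripa", "buff_1_ripa", "buff_2_ripa")

# pairing used for watercourse metrics (shade, sinuosity), which are computed
# on the stream itself and therefore identical within each pair
scale_pair <- c(CA = "CA", ripa = "CA",
                buff_1 = "buff_1", buff_1_ripa = "buff_1",
                buff_2 = "buff_2", buff_2_ripa = "buff_2")

#' Build the six spatial-scale footprints of a site
#'
#' Derives, from the catchment mask, the site location and the upstream
#' network, the boolean footprints `CA`, `buff_1`, `buff_2`, `ripa`,
#' `buff_1_ripa`, `buff_2_ripa`.  Discs are centred at the measurement site
#' and clipped to the catchment; the riparian corridor is the set of cells
#' within `corridor` metres of the upstream network, clipped to the
#' catchment; `buff_k_ripa` is the cellwise intersection of `ripa` and
#' `buff_k`.
#'
#' @param catchment_mask Logical matrix (dim of `template`): upstream
#'   catchment of the site.
#' @param network `river_network`.
#' @param site_id Site identifier.
#' @param template [raster_grid] supplying the georeference.
#' @param radii Buffer radii in metres (default 1 km and 2 km).
#' @param corridor Riparian corridor half-width per side in metres (50).
#' @return Named list of six logical matrices (a `scale_mask_set`).
#' @export
build_scale_masks <- function(catchment_mask, network, site_id, template,
                              radii = c(1000, 2000), corridor = 50) {
  site <- network$sites[network$sites$site_id == site_id, ]
  if (nrow(site) != 1) stopf("build_scale_masks: unknown site '%s'", site_id)
  ids <- upstream_reach_ids(network$reaches, site$reach_id)
  rip <- matrix(FALSE, nrow(template$values), ncol(template$values))
  for (rid in ids) {
    rip <- rip | corridor_mask(template, network$reaches[[rid]]$xy, corridor)
  }
  rip <- rip & catchment_mask
  b1 <- disc_mask(template, site$x, site$y, radii[1]) & catchment_mask
  b2 <- disc_mask(template, site$x, site$y, radii[2]) & catchment_mask
  out <- list(CA = catchment_mask, buff_1 = b1, buff_2 = b2,
              ripa = rip, buff_1_ripa = rip & b1, buff_2_ripa = rip & b2)
  class(out) <- "scale_mask_set"
  out
}

#' Land-cover proportions within a footprint
#'
#' Percentage of each of the eight aggregated land-cover categories among
#' the non-missing cells of the footprint.  Percentages sum to 100.
#'
#' @param landcover [raster_grid] of integer category codes.
#' @param scale_mask Logical footprint matrix.
#' @param classes Named integer vector mapping category names to codes
#'   (default [landcover_classes()]).
#' @return Named numeric vector of percentages (one per category).
#' @export
landcover_proportions <- function(landcover, scale_mask, classes = landcover_classes()) {
  v <- landcover$values[scale_mask]
  v <- v[!is.na(v)]
  if (!length(v)) stopf("landcover_proportions: footprint contains no classified cells")
  unknown <- setdiff(unique(v), classes)
  if (length(unknown))
    stopf("landcover_proportions: unmapped land-cover code(s): %s",
          paste(sort(unknown), collapse = ", "))
  counts <- vapply(classes, function(code) sum(v == code), 0)
  100 * counts / length(v)
}

#' The eight aggregated land-cover categories
#'
#' Category names follow the predictor symbols of the analysis table:
#' HERBA (herbaceous), BROAD (broadleaved forest), NEEDLE (needle-leaved
#' forest), AGRI (agricultural land), WATER (water and flooded land), ARTI
#' (artificialised land), FORESTS (mixed forest), OTHER (mixed vegetation,
#' bare soil, regrowth).
#'
#' @return Named integer vector of raster codes.
#' @export
landcover_classes <- function() {
  c(HERBA = 1L, BROAD = 2L, NEEDLE = 3L, AGRI = 4L,
    WATER = 5L, ARTI = 6L, FORESTS = 7L, OTHER = 8L)
}
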