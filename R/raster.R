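#' Planar raster grids
#'
#' A `raster_grid` is the package's lightweight raster container: a numeric
#' matrix plus a planar georeference (lower-left corner, square cell size in
#' metres) and a no-data sentinel.  Matrix row 1 is the *top* (northernmost)
#' row, matching the ESRI ASCII grid layout, and cell values are sampled at
#' cell centres.
#'
#' @param values Numeric matrix (row 1 = northernmost row).
#' @param xll,yll Planar coordinates (m) of the lower-left corner of the grid.
#' @param cellsize Cell edge length in metres (> 0).
#' @param nodata No-data sentinel written to disk; `NA` in memory.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cellsize = 1, nodata = -9999) {
  if (!is.matrix(values)) stopf("raster values must be a matrix")
  if (!is_number(cellsize) || cellsize <= 0) stopf("cellsize must be a positive number")
  structure(
    list(values = values, xll = xll, yll = yll,
         cellsize = cellsize, nodata = nodata),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d rows x %d cols, cell %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  v <- x$values[is.finite(x$values)]
  if (length(v)) cat(sprintf("  values: [%g, %g]\n", min(v), max(v)))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

# Planar x coordinate of every column centre / y of every row centre.
raster_xcoords <- function(g) g$xll + (seq_len(ncol(g$values)) - 0.5) * g$cellsize
raster_ycoords <- function(g) g$yll + (nrow(g$values) - seq_len(nrow(g$values)) + 0.5) * g$cellsize

# Matrices of cell-centre coordinates (same dim as values).
raster_coord_matrices <- function(g) {
  xs <- raster_xcoords(g); ys <- raster_ycoords(g)
  list(x = matrix(xs, nrow(g$values), ncol(g$values), byrow = TRUE),
       y = matrix(ys, nrow(g$values), ncol(g$values)))
}

# Row/col index of the cell containing planar point (x, y); NA outside.
raster_cell_index <- function(g, x, y) {
  col <- floor((x - g$xll) / g$cellsize) + 1
  row <- nrow(g$values) - floor((y - g$yll) / g$cellsize)
  bad <- col < 1 | col > ncol(g$values) | row < 1 | row > nrow(g$values)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by the data block.
#' No-data cells become `NA`.
#'
#' @param path Path to a `.asc` file.
#' @return A [raster_grid].
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  expected <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  for (i in seq_len(6)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L || is.na(suppressWarnings(as.numeric(parts[2]))))
      stopf("malformed ESRI ASCII header at line %d of %s: '%s'", i, path, lines[i])
    key <- tolower(parts[1])
    if (key != expected[i])
      stopf("malformed ESRI ASCII header at line %d: expected '%s', found '%s'",
            i, expected[i], key)
    hdr[[key]] <- as.numeric(parts[2])
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stopf("ESRI ASCII data block of %s has %d values, expected %d",
          path, length(vals), hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  raster_grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
              cellsize = hdr$cellsize, nodata = hdr$nodata_value)
}

#' Write an ESRI ASCII grid
#'
#' @param g A [raster_grid].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_esri_ascii <- function(g, path) {
  stopifnot(inherits(g, "raster_grid"))
  m <- g$values
  m[is.na(m)] <- g$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", g$xll),
    sprintf("yllcorner %.10g", g$yll),
    sprintf("cellsize %.10g", g$cellsize),
    sprintf("NODATA_value %.10g", g$nodata)
  )
  rows <- apply(m, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# --- geometry helpers used by the zonal-statistics code ------------------

# Sample the raster at a planar point; points on a cell boundary (or whose
# cell is no-data) fall back to the nearest valid 8-neighbour.
raster_value_at <- function(g, x, y) {
  idx <- raster_cell_index(g, x, y)
  if (!anyNA(idx) && !is.na(g$values[idx])) return(g$values[idx])
  if (anyNA(idx)) return(NA_real_)
  for (d in list(c(-1, 0), c(0, -1), c(0, 1), c(1, 0),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
    r <- idx[1] + d[1]; cl <- idx[2] + d[2]
    if (r >= 1 && r <= nrow(g$values) && cl >= 1 && cl <= ncol(g$values) &&
        !is.na(g$values[r, cl])) return(g$values[r, cl])
  }
  NA_real_
}

# Squared distance from points (px, py) to segment (x1,y1)-(x2,y2), vectorised
# over points.
point_segment_dist2 <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return((px - x1)^2 + (py - y1)^2)
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  t <- pmin(1, pmax(0, t))
  (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
}

# Boolean matrix (dim of template) TRUE where the cell centre lies within
# `halfwidth` metres of the polyline `xy` (two-column matrix of vertices).
corridor_mask <- function(template, xy, halfwidth) {
  cm <- raster_coord_matrices(template)
  out <- matrix(FALSE, nrow(template$values), ncol(template$values))
  xs <- raster_xcoords(template); ys <- raster_ycoords(template)
  for (i in seq_len(nrow(xy) - 1)) {
    x1 <- xy[i, 1]; y1 <- xy[i, 2]; x2 <- xy[i + 1, 1]; y2 <- xy[i + 1, 2]
    # restrict to the segment's bounding box padded by halfwidth
    cs <- which(xs >= min(x1, x2) - halfwidth & xs <= max(x1, x2) + halfwidth)
    rs <- which(ys >= min(y1, y2) - halfwidth & ys <= max(y1, y2) + halfwidth)
    if (!length(cs) || !length(rs)) next
    px <- cm$x[rs, cs, drop = FALSE]; py <- cm$y[rs, cs, drop = FALSE]
    d2 <- point_segment_dist2(px, py, x1, y1, x2, y2)
    hit <- d2 <= halfwidth^2
    out[rs, cs] <- out[rs, cs] | hit
  }
  out
}

# Boolean matrix TRUE where the cell centre lies inside the disc of `radius`
# metres about (cx, cy).
disc_mask <- function(template, cx, cy, radius) {
  cm <- raster_coord_matrices(template)
  (cm$x - cx)^2 + (cm$y - cy)^2 <= radius^2
}

# Ray-casting point-in-polygon; poly is a two-column matrix (closed or open).
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) { poly <- poly[-n, , drop = FALSE]; n <- n - 1 }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Rasterise a polygon to a boolean matrix on the template grid.
polygon_mask <- function(template, poly) {
  cm <- raster_coord_matrices(template)
  matrix(point_in_polygon(as.vector(cm$x), as.vector(cm$y), poly),
         nrow(template$values), ncol(template$values))
}

# Length of a polyline given as a two-column vertex matrix.
polyline_length <- function(xy) {
  if (nrow(xy) < 2) return(0)
  sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
}
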