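# Polygon and pixel geometry: ring handling, even-odd point-in-polygon,
# map <-> pixel index conversion. Pixel membership follows the
# pixel-center-in-polygon rule with half-open pixel extents.

# Ensure the ring is explicitly closed (first vertex repeated last).
.closeRing <- function(p) {
  if (!all(p[1, ] == p[nrow(p), ])) p <- rbind(p, p[1, ])
  p
}

# Shoelace signed area of a closed ring.
.ringArea <- function(ring) {
  n <- nrow(ring)
  x <- ring[, 1]; y <- ring[, 2]
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

# Proper-intersection test between segments (p1,p2) and (p3,p4), excluding
# shared endpoints; used for the polygon simplicity check.
.segmentsCross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# TRUE if the closed ring has any pair of non-adjacent properly crossing
# edges. O(n^2); plot polygons are small.
.ringSelfIntersects <- function(ring) {
  n <- nrow(ring) - 1L              # number of edges
  if (n < 4L) return(FALSE)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (j == i + 1L || (i == 1L && j == n)) next   # adjacent edges share a vertex
      if (.segmentsCross(ring[i, ], ring[i + 1L, ], ring[j, ], ring[j + 1L, ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Even-odd point-in-polygon test
#'
#' Vectorized ray-casting (even-odd rule). Points exactly on an edge are
#' resolved by the half-open crossing convention (\code{y1 > py} vs
#' \code{y2 > py}), which is deterministic and partition-consistent: a point
#' on the shared edge of two polygons that partition a region is counted in
#' exactly one of them.
#'
#' @param px,py point coordinates (equal-length numeric vectors).
#' @param polygon n x 2 vertex matrix (columns easting, northing), open or
#'   closed.
#' @return logical vector.
#' @export
pointInPolygon <- function(px, py, polygon) {
  ring <- .closeRing(polygon)
  n <- nrow(ring) - 1L
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1L, 1]; y2 <- ring[i + 1L, 2]
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      hit <- px[crosses] < xint
      inside[crosses] <- xor(inside[crosses], hit)
    }
  }
  inside
}

#' Convert between map coordinates and pixel indices
#'
#' \code{mapToPixel} returns the (row, col) index of the pixel whose
#' half-open extent contains the point; \code{pixelToMap} returns the map
#' coordinates of a pixel center. The two are inverse on pixel centers.
#'
#' @param transform a \linkS4class{GeoTransform}.
#' @param e,n easting/northing (m).
#' @param row,col 1-based pixel indices.
#' @return \code{mapToPixel}: data.frame with columns row, col;
#'   \code{pixelToMap}: data.frame with columns e, n.
#' @export
mapToPixel <- function(transform, e, n) {
  ps <- transform@pixelSize
  data.frame(row = floor((transform@originN - n) / ps) + 1,
             col = floor((e - transform@originE) / ps) + 1)
}

#' @rdname mapToPixel
#' @export
pixelToMap <- function(transform, row, col) {
  ps <- transform@pixelSize
  data.frame(e = transform@originE + (col - 0.5) * ps,
             n = transform@originN - (row - 0.5) * ps)
}

# Row/col indices (restricted to the polygon bounding box) of pixels whose
# centers fall inside the polygon. dims = c(nrow, ncol) of the raster.
.polygonPixels <- function(transform, dims, polygon) {
  ps <- transform@pixelSize
  ring <- .closeRing(polygon)
  cmin <- max(1L, floor((min(ring[, 1]) - transform@originE) / ps) + 1L)
  cmax <- min(dims[2], ceiling((max(ring[, 1]) - transform@originE) / ps))
  rmin <- max(1L, floor((transform@originN - max(ring[, 2])) / ps) + 1L)
  rmax <- min(dims[1], ceiling((transform@originN - min(ring[, 2])) / ps))
  if (cmin > cmax || rmin > rmax)
    return(cbind(row = integer(0), col = integer(0)))
  rows <- seq.int(rmin, rmax)
  cols <- seq.int(cmin, cmax)
  grid <- expand.grid(row = rows, col = cols)
  ctr <- pixelToMap(transform, grid$row, grid$col)
  keep <- pointInPolygon(ctr$e, ctr$n, ring)
  cbind(row = grid$row[keep], col = grid$col[keep])
}
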