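# Terrain and crop-surface modelling: DTM interpolation from bare-soil
# elevations, CSM = DSM - DTM, height-threshold canopy segmentation, and
# per-plot canopy height / coverage / volume.

# Thin-plate-spline interpolation of scattered (e, n, z) samples, evaluated
# at arbitrary points. Exact at the samples and exactly reproduces any
# plane (the affine polynomial part). Coordinates are rescaled to a unit box
# before solving for conditioning; the interpolant is unchanged by that
# reparameterization.
.tpsFit <- function(e, n, z) {
  s <- max(max(e) - min(e), max(n) - min(n), 1e-9)
  e0 <- min(e); n0 <- min(n)
  x <- (e - e0) / s; y <- (n - n0) / s
  m <- length(x)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  K <- ifelse(d2 == 0, 0, 0.5 * d2 * log(d2))    # r^2 log r
  P <- cbind(1, x, y)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(z, 0, 0, 0)
  sol <- solve(A, rhs)
  list(w = sol[seq_len(m)], a = sol[m + 1:3], x = x, y = y,
       e0 = e0, n0 = n0, s = s)
}

.tpsEval <- function(fit, e, n, chunk = 40000L) {
  x <- (e - fit$e0) / fit$s; y <- (n - fit$n0) / fit$s
  out <- numeric(length(x))
  for (start in seq(1L, length(x), by = chunk)) {
    i <- start:min(start + chunk - 1L, length(x))
    d2 <- outer(x[i], fit$x, "-")^2 + outer(y[i], fit$y, "-")^2
    K <- ifelse(d2 == 0, 0, 0.5 * d2 * log(d2))
    out[i] <- K %*% fit$w + fit$a[1] + fit$a[2] * x[i] + fit$a[3] * y[i]
  }
  out
}

#' Build a digital terrain model from bare-soil elevations
#'
#' Interpolates the DSM elevations observed at bare-soil locations over the
#' whole grid with an exact thin-plate-spline interpolant: the DTM equals
#' the DSM at every soil sample used, and a planar terrain sampled at
#' non-collinear soil points is reproduced exactly everywhere. Soil support
#' can be given as a logical soil mask (TRUE = bare soil), as a two-column
#' matrix of map coordinates, or -- the default in the pipeline -- sampled
#' automatically from pixels outside all plot polygons.
#'
#' When more than \code{maxPoints} soil pixels are available, an
#' evenly-spaced deterministic subsample of that size is used to keep the
#' interpolation solve small.
#'
#' @param dsm an \linkS4class{ElevationGrid} with role DSM.
#' @param soilMask logical matrix matching the DSM, TRUE = bare soil; or
#'   NULL.
#' @param soilPoints n x 2 matrix of easting/northing soil locations; or
#'   NULL.
#' @param plots a \linkS4class{PlotSet}: soil pixels are those outside all
#'   plot polygons (used when neither mask nor points are given).
#' @param maxPoints cap on the number of soil samples entering the solve.
#' @return an \linkS4class{ElevationGrid} with role DTM.
#' @export
buildDTM <- function(dsm, soilMask = NULL, soilPoints = NULL, plots = NULL,
                     maxPoints = 250L) {
  stopifnot(is(dsm, "ElevationGrid"))
  tr <- dsm@transform
  nr <- nrow(dsm@values); nc <- ncol(dsm@values)
  if (is.null(soilMask) && is.null(soilPoints)) {
    if (is.null(plots))
      stop("one of soilMask, soilPoints or plots must be given")
    soilMask <- matrix(TRUE, nr, nc)
    m <- plotMeta(plots)
    for (i in which(m$role == "plot")) {
      px <- .polygonPixels(tr, c(nr, nc), plots@polygons[[i]])
      if (nrow(px)) soilMask[cbind(px[, "row"], px[, "col"])] <- FALSE
    }
  }
  if (!is.null(soilMask)) {
    soilMask <- soilMask & !dsm@nodata
    idx <- which(soilMask, arr.ind = TRUE)
    ctr <- pixelToMap(tr, idx[, 1], idx[, 2])
    e <- ctr$e; n <- ctr$n
    z <- dsm@values[idx]
  } else {
    rc <- mapToPixel(tr, soilPoints[, 1], soilPoints[, 2])
    keep <- rc$row >= 1 & rc$row <= nr & rc$col >= 1 & rc$col <= nc
    rc <- rc[keep, , drop = FALSE]
    e <- soilPoints[keep, 1]; n <- soilPoints[keep, 2]
    z <- dsm@values[cbind(rc$row, rc$col)]
  }
  if (length(z) > maxPoints) {
    pick <- unique(round(seq(1, length(z), length.out = maxPoints)))
    e <- e[pick]; n <- n[pick]; z <- z[pick]
  }
  if (length(z) < 3)
    stop("insufficient soil support: need >= 3 soil samples, got ", length(z))
  if (qr(cbind(1, e, n))$rank < 3)
    stop("insufficient soil support: soil samples are collinear")
  fit <- .tpsFit(e, n, z)
  cols <- rep(seq_len(nc), each = nr)
  rows <- rep(seq_len(nr), nc)
  ctr <- pixelToMap(tr, rows, cols)
  dtm <- matrix(.tpsEval(fit, ctr$e, ctr$n), nr, nc)
  ElevationGrid(dtm, tr, role = "DTM", nodata = dsm@nodata)
}

#' Crop surface model: CSM = DSM - DTM
#'
#' Per-pixel subtraction of the terrain from the surface model, yielding
#' canopy height above ground level. Nodata propagates from either input.
#'
#' @param dsm,dtm \linkS4class{ElevationGrid}s sharing shape and transform.
#' @return an \linkS4class{ElevationGrid} with role CSM.
#' @export
computeCSM <- function(dsm, dtm) {
  stopifnot(is(dsm, "ElevationGrid"), is(dtm, "ElevationGrid"))
  if (!identical(dim(dsm@values), dim(dtm@values)))
    stop("DSM and DTM shapes differ")
  if (!isTRUE(all.equal(dsm@transform, dtm@transform)))
    stop("DSM and DTM geotransforms differ")
  nodata <- dsm@nodata | dtm@nodata
  vals <- dsm@values - dtm@values
  vals[nodata] <- 0
  ElevationGrid(vals, dsm@transform, role = "CSM", nodata = nodata)
}

#' Segment canopy at a height threshold
#'
#' Classifies pixels with CSM strictly greater than the threshold (default
#' 0.15 m AGL) as canopy; everything at or below -- including weeds and
#' other low noise -- is non-canopy. The comparison is strict so the
#' boundary case is deterministic. The mask's complement doubles as a soil
#' mask for vegetation-index zonal statistics.
#'
#' @param csm an \linkS4class{ElevationGrid} with role CSM.
#' @param threshold height threshold in m AGL, >= 0.
#' @return a \linkS4class{CanopyMask}.
#' @export
segmentCanopy <- function(csm, threshold = 0.15) {
  stopifnot(is(csm, "ElevationGrid"))
  if (csm@role != "CSM")
    stop("canopy segmentation requires a CSM (got role ", csm@role, ")")
  if (threshold < 0) stop("threshold must be >= 0")
  vals <- csm@values > threshold & !csm@nodata
  new("CanopyMask", values = vals, threshold = threshold,
      transform = csm@transform)
}

#' Per-plot canopy height, coverage and volume
#'
#' For each plot polygon: CH_uas is the mean CSM over in-plot canopy pixels
#' (0 when the plot has none); CC is the in-plot canopy pixel count times
#' the pixel area; PV = CH_uas x CC. With a 0.005 m GSD the pixel area is
#' 25e-6 m^2.
#'
#' @param csm an \linkS4class{ElevationGrid} with role CSM.
#' @param mask a \linkS4class{CanopyMask} on the same grid.
#' @param plots a \linkS4class{PlotSet} (only role == "plot" rows are used).
#' @param chStat statistic for CH_uas over in-plot canopy pixels: "mean"
#'   (default, so PV approximates the integral of height over covered
#'   area), "max", or a quantile probability in (0, 1).
#' @return data.frame with columns plot_id, ch_uas, cc, pv, n_canopy.
#' @export
plotCanopyMetrics <- function(csm, mask, plots, chStat = "mean") {
  stopifnot(is(csm, "ElevationGrid"), is(mask, "CanopyMask"))
  if (!identical(dim(csm@values), dim(mask@values)))
    stop("CSM and mask shapes differ")
  tr <- csm@transform
  pixArea <- tr@pixelSize^2
  dims <- dim(csm@values)
  m <- plotMeta(plots)
  keep <- which(m$role == "plot")
  out <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    px <- .polygonPixels(tr, dims, plots@polygons[[i]])
    if (nrow(px) == 0)
      stop("plot ", m$plot_id[i], " lies entirely outside the raster")
    idx <- cbind(px[, "row"], px[, "col"])
    can <- mask@values[idx] & !csm@nodata[idx]
    nCan <- sum(can)
    ch <- if (nCan == 0) 0 else {
      h <- csm@values[idx][can]
      if (identical(chStat, "mean")) mean(h)
      else if (identical(chStat, "max")) max(h)
      else stats::quantile(h, probs = as.numeric(chStat), names = FALSE)
    }
    cc <- nCan * pixArea
    out[[k]] <- data.frame(plot_id = m$plot_id[i], ch_uas = ch, cc = cc,
                           pv = ch * cc, n_canopy = nCan,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
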