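# Radiometric correction against the white reference panel, vegetation-index
# grids, and nearest-neighbour resolution degradation.

#' Radiometric correction against a white reference panel
#'
#' Scales each band by \code{panelReflectance / mean(panel pixels)} so that,
#' after correction, the panel-region mean of every band equals the panel's
#' known reflectance. This is a single global gain per band (one panel per
#' flight; no spatial vignetting model).
#'
#' @param stack a \linkS4class{BandStack} (reflectance or digital numbers).
#' @param panelPolygon n x 2 polygon of the panel region (map coords).
#' @param panelReflectance known panel reflectance, default 0.99.
#' @return a corrected \linkS4class{BandStack}.
#' @export
panelCorrect <- function(stack, panelPolygon, panelReflectance = 0.99) {
  stopifnot(is(stack, "BandStack"))
  tr <- stack@transform
  dims <- dim(stack@bands[[1]])
  px <- .polygonPixels(tr, dims, panelPolygon)
  if (nrow(px) == 0) stop("no panel pixels: panel polygon does not cover any pixel center")
  idx <- cbind(px[, "row"], px[, "col"])
  valid <- !stack@nodata[idx]
  if (!any(valid)) stop("no panel pixels: all panel pixels are nodata")
  bands <- stack@bands
  for (b in names(bands)) {
    pm <- mean(bands[[b]][idx][valid])
    if (!is.finite(pm) || pm <= 0)
      stop("panel mean for band ", b, " is not positive; cannot correct")
    bands[[b]] <- bands[[b]] * (panelReflectance / pm)
  }
  BandStack(bands, tr, stack@nodata)
}

#' Compute a normalized-difference vegetation-index grid
#'
#' GRVI = (G - R) / (G + R); NDVI = (NIR - R) / (NIR + R);
#' NDRE = (NIR - RE) / (NIR + RE). Pixels where the denominator is zero (or
#' either operand is nodata) are masked nodata rather than set to +/-Inf.
#'
#' @param stack a \linkS4class{BandStack} of reflectances.
#' @param indexName "GRVI", "NDVI" or "NDRE" (for NIRv see
#'   \code{\link{computeNIRv}}).
#' @return a \linkS4class{ValueGrid}.
#' @export
computeVI <- function(stack, indexName) {
  stopifnot(is(stack, "BandStack"))
  pair <- switch(indexName,
                 GRVI = c("G", "R"),
                 NDVI = c("NIR", "R"),
                 NDRE = c("NIR", "RE"),
                 stop("unknown index '", indexName,
                      "'; expected GRVI, NDVI, NDRE or NIRv (computeNIRv)"))
  a <- stack@bands[[pair[1]]]
  b <- stack@bands[[pair[2]]]
  den <- a + b
  nodata <- stack@nodata | den == 0
  vals <- matrix(0, nrow(a), ncol(a))
  ok <- !nodata
  vals[ok] <- (a[ok] - b[ok]) / den[ok]
  ValueGrid(vals, stack@transform, indexName, nodata)
}

#' Compute the NIRv grid
#'
#' NIRv, the near-infrared reflectance of vegetation, down-weights soil
#' contamination. The default \code{"paper"} variant subtracts 0.08 from the
#' product of the pixel's NIR reflectance and NDVI: \code{NIR * NDVI - 0.08}.
#' The \code{"badgley"} variant applies the offset inside the product,
#' \code{(NDVI - 0.08) * NIR}, matching the index's original formulation;
#' both are retained because the two forms circulate in the literature.
#'
#' @param stack a \linkS4class{BandStack}.
#' @param variant "paper" (default) or "badgley".
#' @return a \linkS4class{ValueGrid} with indexName "NIRv".
#' @export
computeNIRv <- function(stack, variant = c("paper", "badgley")) {
  variant <- match.arg(variant)
  ndvi <- computeVI(stack, "NDVI")
  nir <- stack@bands[["NIR"]]
  vals <- switch(variant,
                 paper = nir * ndvi@values - 0.08,
                 badgley = (ndvi@values - 0.08) * nir)
  vals[ndvi@nodata] <- 0
  ValueGrid(vals, stack@transform, "NIRv", ndvi@nodata)
}

# Core nearest-neighbour resampler on (values, transform): each output pixel
# takes the value of the source pixel containing its center.
.resampleNearestCore <- function(values, nodata, tr, target) {
  ps <- tr@pixelSize
  if (target < ps - 1e-12)
    stop("target pixel size ", target, " m is smaller than source ", ps,
         " m; upsampling is not supported")
  nr <- nrow(values); nc <- ncol(values)
  ncOut <- max(1L, as.integer(ceiling(nc * ps / target - 1e-9)))
  nrOut <- max(1L, as.integer(ceiling(nr * ps / target - 1e-9)))
  ctrE <- tr@originE + (seq_len(ncOut) - 0.5) * target
  ctrN <- tr@originN - (seq_len(nrOut) - 0.5) * target
  srcC <- pmin(pmax(floor((ctrE - tr@originE) / ps) + 1, 1), nc)
  srcR <- pmin(pmax(floor((tr@originN - ctrN) / ps) + 1, 1), nr)
  list(values = values[srcR, srcC, drop = FALSE],
       nodata = nodata[srcR, srcC, drop = FALSE],
       transform = GeoTransform(tr@originE, tr@originN, target))
}

#' Degrade raster resolution by nearest-neighbour resampling
#'
#' Emulates coarser sensors (e.g. degrading a 0.005 m UAS mosaic to a 1.5 m
#' satellite pixel): each output pixel takes the value of the source pixel
#' containing its center, so no new values are introduced. Only degradation
#' (target >= source pixel size) is supported.
#'
#' @param grid a \linkS4class{ValueGrid}, \linkS4class{ElevationGrid} or
#'   \linkS4class{BandStack}.
#' @param targetPixelSize output pixel size, m.
#' @return an object of the same class at the coarser resolution.
#' @export
setGeneric("resampleNearest",
           function(grid, targetPixelSize) standardGeneric("resampleNearest"))

#' @rdname resampleNearest
setMethod("resampleNearest", "ValueGrid", function(grid, targetPixelSize) {
  r <- .resampleNearestCore(grid@values, grid@nodata, grid@transform,
                            targetPixelSize)
  ValueGrid(r$values, r$transform, grid@indexName, r$nodata)
})

#' @rdname resampleNearest
setMethod("resampleNearest", "ElevationGrid", function(grid, targetPixelSize) {
  r <- .resampleNearestCore(grid@values, grid@nodata, grid@transform,
                            targetPixelSize)
  ElevationGrid(r$values, r$transform, role = grid@role, nodata = r$nodata)
})

#' @rdname resampleNearest
setMethod("resampleNearest", "BandStack", function(grid, targetPixelSize) {
  rs <- lapply(grid@bands, function(v)
    .resampleNearestCore(v, grid@nodata, grid@transform, targetPixelSize))
  BandStack(lapply(rs, `[[`, "values"), rs[[1]]$transform, rs[[1]]$nodata)
})
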