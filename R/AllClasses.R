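#' @import methods
NULL

#' Geotransform for north-up square-pixel rasters
#'
#' Maps matrix indices to projected map coordinates (easting/northing in
#' metres). The raster is north-up: row 1 is the northernmost row and row
#' indices increase southward; column indices increase eastward. Pixels are
#' square with side \code{pixelSize}; pixel (r, c) covers the half-open extent
#' \code{[originE + (c-1)*ps, originE + c*ps)} easting and
#' \code{(originN - r*ps, originN - (r-1)*ps]} northing, where \code{originN}
#' is the northing of the top-left raster corner.
#'
#' @slot originE easting of the left (west) raster edge, m.
#' @slot originN northing of the top (north) raster edge, m.
#' @slot pixelSize pixel side length, m (ground sample distance).
#' @export
setClass("GeoTransform",
  representation(originE = "numeric", originN = "numeric",
                 pixelSize = "numeric"),
  prototype(originE = 0, originN = 0, pixelSize = 1))

setValidity("GeoTransform", function(object) {
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive finite number")
  if (length(object@originE) != 1L || !is.finite(object@originE))
    return("originE must be a single finite number")
  if (length(object@originN) != 1L || !is.finite(object@originN))
    return("originN must be a single finite number")
  TRUE
})

#' @describeIn GeoTransform-class constructor.
#' @param originE,originN map coordinates of the top-left raster corner (m).
#' @param pixelSize pixel side length (m).
#' @export
GeoTransform <- function(originE = 0, originN = 0, pixelSize = 1) {
  new("GeoTransform", originE = as.numeric(originE),
      originN = as.numeric(originN), pixelSize = as.numeric(pixelSize))
}

.BAND_NAMES <- c("B", "G", "R", "RE", "NIR")

#' Aligned five-band reflectance stack
#'
#' Holds the blue, green, red, red-edge and near-infrared grids of a
#' multispectral orthomosaic as matrices sharing one geotransform and one
#' nodata mask. Values are unitless reflectance (or raw digital numbers prior
#' to radiometric correction); where valid they must be finite and
#' non-negative.
#'
#' @slot bands named list of matrices, names exactly B, G, R, RE, NIR.
#' @slot transform a \linkS4class{GeoTransform}.
#' @slot nodata logical matrix, TRUE where the pixel carries no data.
#' @export
setClass("BandStack",
  representation(bands = "list", transform = "GeoTransform",
                 nodata = "matrix"))

setValidity("BandStack", function(object) {
  if (!identical(names(object@bands), .BAND_NAMES))
    return(sprintf("bands must be named exactly %s in order",
                   paste(.BAND_NAMES, collapse = ", ")))
  dims <- lapply(object@bands, dim)
  if (length(unique(dims)) != 1L)
    return("all bands must share the same dimensions")
  if (!identical(dim(object@nodata), dims[[1]]))
    return("nodata mask must match band dimensions")
  if (!is.logical(object@nodata))
    return("nodata mask must be logical")
  for (b in .BAND_NAMES) {
    v <- object@bands[[b]][!object@nodata]
    if (any(!is.finite(v)) || any(v < 0))
      return(sprintf("band %s has non-finite or negative values outside the nodata mask", b))
  }
  TRUE
})

#' @describeIn BandStack-class constructor; \code{bands} may be in any order
#'   but must contain exactly B, G, R, RE, NIR.
#' @param bands named list of five numeric matrices.
#' @param transform a \linkS4class{GeoTransform}.
#' @param nodata optional logical matrix (default: all valid).
#' @export
BandStack <- function(bands, transform, nodata = NULL) {
  if (!all(sort(names(bands)) == sort(.BAND_NAMES)))
    stop("expected 5 bands named ", paste(.BAND_NAMES, collapse = ", "),
         "; got ", length(bands), " band(s): ",
         paste(names(bands), collapse = ", "))
  bands <- bands[.BAND_NAMES]
  if (is.null(nodata))
    nodata <- matrix(FALSE, nrow(bands[[1]]), ncol(bands[[1]]))
  new("BandStack", bands = bands, transform = transform, nodata = nodata)
}

#' Single-band elevation surface
#'
#' An elevation raster in metres with an explicit role: \code{DSM} (digital
#' surface model, metres above the vertical datum), \code{DTM} (digital
#' terrain model, same datum) or \code{CSM} (crop surface model, metres above
#' ground level, i.e. DSM - DTM).
#'
#' @slot values numeric matrix of elevations (m).
#' @slot role one of "DSM", "DTM", "CSM".
#' @slot transform a \linkS4class{GeoTransform}.
#' @slot nodata logical matrix.
#' @export
setClass("ElevationGrid",
  representation(values = "matrix", role = "character",
                 transform = "GeoTransform", nodata = "matrix"))

setValidity("ElevationGrid", function(object) {
  if (length(object@role) != 1L || !object@role %in% c("DSM", "DTM", "CSM"))
    return("role must be one of DSM, DTM, CSM")
  if (!identical(dim(object@values), dim(object@nodata)))
    return("nodata mask must match value dimensions")
  v <- object@values[!object@nodata]
  if (any(!is.finite(v)))
    return("elevation values outside the nodata mask must be finite")
  TRUE
})

#' @describeIn ElevationGrid-class constructor.
#' @param values numeric matrix (m).
#' @param transform a \linkS4class{GeoTransform}.
#' @param role "DSM", "DTM" or "CSM".
#' @param nodata optional logical matrix (default: all valid).
#' @export
ElevationGrid <- function(values, transform, role = "DSM", nodata = NULL) {
  if (is.null(nodata)) nodata <- matrix(FALSE, nrow(values), ncol(values))
  new("ElevationGrid", values = values, role = role,
      transform = transform, nodata = nodata)
}

#' Vegetation-index grid
#'
#' A per-pixel unitless index surface. For the normalized-difference indices
#' (GRVI, NDVI, NDRE) valid values necessarily lie in [-1, 1]; NIRv is
#' unbounded below.
#'
#' @slot values numeric matrix of index values.
#' @slot indexName one of "GRVI", "NDVI", "NDRE", "NIRv".
#' @slot transform a \linkS4class{GeoTransform}.
#' @slot nodata logical matrix (TRUE where undefined, e.g. zero denominator).
#' @export
setClass("ValueGrid",
  representation(values = "matrix", indexName = "character",
                 transform = "GeoTransform", nodata = "matrix"))

setValidity("ValueGrid", function(object) {
  if (length(object@indexName) != 1L ||
      !object@indexName %in% c("GRVI", "NDVI", "NDRE", "NIRv"))
    return("indexName must be one of GRVI, NDVI, NDRE, NIRv")
  if (!identical(dim(object@values), dim(object@nodata)))
    return("nodata mask must match value dimensions")
  v <- object@values[!object@nodata]
  if (any(!is.finite(v)))
    return("index values outside the nodata mask must be finite")
  if (object@indexName %in% c("GRVI", "NDVI", "NDRE") &&
      length(v) && (min(v) < -1 - 1e-9 || max(v) > 1 + 1e-9))
    return(sprintf("%s values must lie in [-1, 1]", object@indexName))
  TRUE
})

#' @describeIn ValueGrid-class constructor.
#' @param values numeric matrix.
#' @param transform a \linkS4class{GeoTransform}.
#' @param indexName index identifier.
#' @param nodata optional logical matrix.
#' @export
ValueGrid <- function(values, transform, indexName, nodata = NULL) {
  if (is.null(nodata)) nodata <- matrix(FALSE, nrow(values), ncol(values))
  new("ValueGrid", values = values, indexName = indexName,
      transform = transform, nodata = nodata)
}

#' Binary canopy mask
#'
#' Per-pixel canopy / non-canopy classification of a crop surface model:
#' canopy wherever CSM strictly exceeds the height threshold (m above ground
#' level). The complement doubles as a soil mask.
#'
#' @slot values logical matrix, TRUE = canopy.
#' @slot threshold height threshold in m AGL.
#' @slot transform a \linkS4class{GeoTransform}.
#' @export
setClass("CanopyMask",
  representation(values = "matrix", threshold = "numeric",
                 transform = "GeoTransform"))

setValidity("CanopyMask", function(object) {
  if (!is.logical(object@values))
    return("mask values must be logical")
  if (length(object@threshold) != 1L || !is.finite(object@threshold) ||
      object@threshold < 0)
    return("threshold must be a single non-negative number")
  TRUE
})

#' Plot polygon layer with trial metadata
#'
#' A set of field-plot polygons in projected map coordinates, each carrying a
#' plot identifier, entry (genotype) identifier and replicate index. Polygons
#' must be simple (non-self-intersecting) with positive area; plot_ids must
#' be unique. Rows with \code{role != "plot"} (e.g. the radiometric reference
#' panel, \code{role = "panel"}) are carried alongside the plots.
#'
#' @slot polygons list of n x 2 numeric matrices (columns easting, northing);
#'   rings may be open or explicitly closed (first vertex repeated last).
#' @slot meta data.frame with columns plot_id, entry, replicate, role.
#' @export
setClass("PlotSet",
  representation(polygons = "list", meta = "data.frame"))

setValidity("PlotSet", function(object) {
  m <- object@meta
  need <- c("plot_id", "entry", "replicate", "role")
  if (!all(need %in% names(m)))
    return(paste("meta must have columns", paste(need, collapse = ", ")))
  if (length(object@polygons) != nrow(m))
    return("one polygon per metadata row required")
  dup <- unique(m$plot_id[duplicated(m$plot_id)])
  if (length(dup))
    return(paste("duplicate plot_id:", paste(dup, collapse = ", ")))
  for (i in seq_along(object@polygons)) {
    p <- object@polygons[[i]]
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L)
      return(sprintf("polygon for plot %s must be an n x 2 matrix with n >= 3",
                     m$plot_id[i]))
    ring <- .closeRing(p)
    if (nrow(unique(ring[-nrow(ring), , drop = FALSE])) < 3L)
      return(sprintf("polygon for plot %s is degenerate", m$plot_id[i]))
    if (.ringSelfIntersects(ring))
      return(sprintf("polygon for plot %s is self-intersecting", m$plot_id[i]))
    if (abs(.ringArea(ring)) <= 0)
      return(sprintf("polygon for plot %s has zero area", m$plot_id[i]))
  }
  TRUE
})

#' @describeIn PlotSet-class constructor.
#' @param polygons list of n x 2 coordinate matrices.
#' @param meta data.frame with plot_id, entry, replicate (role optional,
#'   default "plot").
#' @export
PlotSet <- function(polygons, meta) {
  meta <- as.data.frame(meta)
  if (is.null(meta$role)) meta$role <- "plot"
  meta$plot_id <- as.character(meta$plot_id)
  rownames(meta) <- NULL
  new("PlotSet", polygons = polygons, meta = meta)
}

#' Scene rendering specification
#'
#' Parameters controlling how a synthetic field scene is rasterized: ground
#' sample distance, additive reflectance noise, elevation noise and
#' quantization, the white-reference-panel region and reflectance, per-band
#' sensor gains, terrain shape, and the extent buffer around the plots.
#'
#' @slot gsd ground sample distance, m/pixel.
#' @slot noiseSd per-band additive Gaussian reflectance noise SD (unitless).
#' @slot elevNoiseSd additive Gaussian elevation noise SD (m).
#' @slot elevQuantum elevation quantization step (m); rendered surfaces are
#'   rounded to this grid, emulating finite sensor precision.
#' @slot panelRegion 4+ x 2 matrix: white-panel polygon, or 0-row matrix to
#'   auto-place the panel in the buffer strip southwest of the plots.
#' @slot panelReflectance panel reflectance, default 0.99.
#' @slot bandGain named per-band multiplicative sensor gain (1 = calibrated).
#' @slot terrainBase,terrainSlopeE,terrainSlopeN planar terrain: elevation at
#'   the scene's southwest corner (m) and west-east / south-north grades
#'   (m/m).
#' @slot buffer bare-ground margin around the plot bounding box (m).
#' @export
setClass("SceneSpec",
  representation(gsd = "numeric", noiseSd = "numeric", elevNoiseSd = "numeric",
                 elevQuantum = "numeric", panelRegion = "matrix",
                 panelReflectance = "numeric", bandGain = "numeric",
                 terrainBase = "numeric", terrainSlopeE = "numeric",
                 terrainSlopeN = "numeric", buffer = "numeric"),
  prototype(gsd = 0.05, noiseSd = 0.01, elevNoiseSd = 0.005,
            elevQuantum = 0.001, panelRegion = matrix(numeric(0), 0, 2),
            panelReflectance = 0.99,
            bandGain = c(B = 1, G = 1, R = 1, RE = 1, NIR = 1),
            terrainBase = 100, terrainSlopeE = 0.01, terrainSlopeN = 0,
            buffer = 2))

setValidity("SceneSpec", function(object) {
  if (object@gsd <= 0) return("gsd must be > 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@elevNoiseSd < 0) return("elevNoiseSd must be >= 0")
  if (object@elevQuantum <= 0) return("elevQuantum must be > 0")
  if (!identical(names(object@bandGain), .BAND_NAMES))
    return("bandGain must be named B, G, R, RE, NIR")
  if (any(object@bandGain <= 0)) return("bandGain must be positive")
  if (object@panelReflectance <= 0) return("panelReflectance must be > 0")
  TRUE
})

#' @describeIn SceneSpec-class constructor with field defaults (5 cm GSD,
#'   1 percent reflectance noise, 1 mm elevation quantum, 1 percent terrain
#'   grade).
#' @param gsd,noiseSd,elevNoiseSd,elevQuantum,panelRegion,panelReflectance
#'   see slots.
#' @param bandGain,terrainBase,terrainSlopeE,terrainSlopeN,buffer see slots.
#' @export
SceneSpec <- function(gsd = 0.05, noiseSd = 0.01, elevNoiseSd = 0.005,
                      elevQuantum = 0.001, panelRegion = NULL,
                      panelReflectance = 0.99,
                      bandGain = c(B = 1, G = 1, R = 1, RE = 1, NIR = 1),
                      terrainBase = 100, terrainSlopeE = 0.01,
                      terrainSlopeN = 0, buffer = 2) {
  if (is.null(panelRegion)) panelRegion <- matrix(numeric(0), 0, 2)
  new("SceneSpec", gsd = gsd, noiseSd = noiseSd, elevNoiseSd = elevNoiseSd,
      elevQuantum = elevQuantum, panelRegion = panelRegion,
      panelReflectance = panelReflectance,
      bandGain = bandGain[.BAND_NAMES],
      terrainBase = terrainBase, terrainSlopeE = terrainSlopeE,
      terrainSlopeN = terrainSlopeN, buffer = buffer)
}

#' Standardized-coefficient linear biomass model
#'
#' A linear above-ground-biomass (AGBM) estimator of the form
#' \deqn{AGBM_{Est} = (\sum_i coef_i x_i + intercept) / divisor}
#' where the x_i are features standardized to zero mean and unit SD. The
#' per-feature centers and scales used for standardization are carried with
#' the model so it can be applied to raw feature rows; frozen literature
#' presets carry NA centers/scales and require pre-standardized input.
#'
#' @slot featureNames ordered feature names.
#' @slot coefficients named numeric, one per feature (standardized scale).
#' @slot intercept numeric scalar.
#' @slot divisor positive scale divisor applied to the linear predictor.
#' @slot centers,scales named numeric standardization parameters (may be NA
#'   for presets fitted elsewhere).
#' @export
setClass("AGBMModel",
  representation(featureNames = "character", coefficients = "numeric",
                 intercept = "numeric", divisor = "numeric",
                 centers = "numeric", scales = "numeric"))

setValidity("AGBMModel", function(object) {
  if (!identical(names(object@coefficients), object@featureNames))
    return("coefficients must align one-to-one with featureNames")
  if (length(object@divisor) != 1L || !is.finite(object@divisor) ||
      object@divisor <= 0)
    return("divisor must be a single positive number")
  if (!identical(names(object@centers), object@featureNames) ||
      !identical(names(object@scales), object@featureNames))
    return("centers and scales must align with featureNames")
  sc <- object@scales[!is.na(object@scales)]
  if (any(sc <= 0)) return("scales must be positive")
  TRUE
})

#' @describeIn AGBMModel-class constructor.
#' @param coefficients named numeric vector of standardized coefficients.
#' @param intercept intercept on the pre-divisor scale.
#' @param divisor positive divisor.
#' @param centers,scales optional named standardization parameters.
#' @export
AGBMModel <- function(coefficients, intercept, divisor = 1,
                      centers = NULL, scales = NULL) {
  fn <- names(coefficients)
  if (is.null(fn)) stop("coefficients must be named")
  if (is.null(centers)) centers <- stats::setNames(rep(NA_real_, length(fn)), fn)
  if (is.null(scales)) scales <- stats::setNames(rep(NA_real_, length(fn)), fn)
  new("AGBMModel", featureNames = fn, coefficients = coefficients,
      intercept = intercept, divisor = divisor,
      centers = centers[fn], scales = scales[fn])
}

#' One-dimensional green-band leaf-type classifier
#'
#' Threshold classifier separating semi-leafless (af) from normal (Af) pea
#' entries on their plot-mean green reflectance.
#'
#' @slot threshold decision threshold in green reflectance units.
#' @slot upperClass label assigned above the threshold.
#' @slot lowerClass label assigned at or below the threshold.
#' @slot classStats data.frame of per-class mean, SD and n.
#' @slot accuracy training accuracy in [0, 1].
#' @export
setClass("LeafTypeModel",
  representation(threshold = "numeric", upperClass = "character",
                 lowerClass = "character", classStats = "data.frame",
                 accuracy = "numeric"))

setValidity("LeafTypeModel", function(object) {
  if (object@accuracy < 0 || object@accuracy > 1)
    return("accuracy must lie in [0, 1]")
  TRUE
})
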