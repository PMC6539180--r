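# Accessor generics and show methods for the core classes.

#' @title Accessors for raster, plot and model objects
#' @description Accessor generics: slot access from user code should go
#'   through these rather than \code{@}.
#' @param x an object of the documented classes.
#' @param ... further arguments for methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridValues", function(x, ...) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setGeneric("gridTransform", function(x) standardGeneric("gridTransform"))
#' @rdname accessors
#' @export
setGeneric("nodataMask", function(x) standardGeneric("nodataMask"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("bandNames", function(x) standardGeneric("bandNames"))
#' @rdname accessors
#' @param band band name (one of B, G, R, RE, NIR).
#' @export
setGeneric("getBand", function(x, band) standardGeneric("getBand"))
#' @rdname accessors
#' @export
setGeneric("gridRole", function(x) standardGeneric("gridRole"))
#' @rdname accessors
#' @export
setGeneric("indexName", function(x) standardGeneric("indexName"))
#' @rdname accessors
#' @export
setGeneric("maskThreshold", function(x) standardGeneric("maskThreshold"))
#' @rdname accessors
#' @export
setGeneric("nPlots", function(x) standardGeneric("nPlots"))
#' @rdname accessors
#' @export
setGeneric("plotIds", function(x) standardGeneric("plotIds"))
#' @rdname accessors
#' @param id plot identifier.
#' @export
setGeneric("plotPolygon", function(x, id) standardGeneric("plotPolygon"))
#' @rdname accessors
#' @export
setGeneric("plotMeta", function(x) standardGeneric("plotMeta"))
#' @rdname accessors
#' @export
setGeneric("modelCoefficients", function(x) standardGeneric("modelCoefficients"))
#' @rdname accessors
#' @export
setGeneric("modelIntercept", function(x) standardGeneric("modelIntercept"))
#' @rdname accessors
#' @export
setGeneric("modelDivisor", function(x) standardGeneric("modelDivisor"))

#' @rdname accessors
setMethod("pixelSize", "GeoTransform", function(x) x@pixelSize)
#' @rdname accessors
setMethod("gridTransform", "BandStack", function(x) x@transform)
#' @rdname accessors
setMethod("gridTransform", "ElevationGrid", function(x) x@transform)
#' @rdname accessors
setMethod("gridTransform", "ValueGrid", function(x) x@transform)
#' @rdname accessors
setMethod("gridTransform", "CanopyMask", function(x) x@transform)
#' @rdname accessors
setMethod("pixelSize", "BandStack", function(x) x@transform@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "ElevationGrid", function(x) x@transform@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "ValueGrid", function(x) x@transform@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "CanopyMask", function(x) x@transform@pixelSize)
#' @rdname accessors
setMethod("nodataMask", "BandStack", function(x) x@nodata)
#' @rdname accessors
setMethod("nodataMask", "ElevationGrid", function(x) x@nodata)
#' @rdname accessors
setMethod("nodataMask", "ValueGrid", function(x) x@nodata)
#' @rdname accessors
setMethod("bandNames", "BandStack", function(x) names(x@bands))
#' @rdname accessors
setMethod("getBand", "BandStack", function(x, band) {
  if (!band %in% names(x@bands))
    stop("unknown band '", band, "'; expected one of ",
         paste(names(x@bands), collapse = ", "))
  x@bands[[band]]
})
#' @rdname accessors
setMethod("gridValues", "ElevationGrid", function(x, ...) x@values)
#' @rdname accessors
setMethod("gridValues", "ValueGrid", function(x, ...) x@values)
#' @rdname accessors
setMethod("gridValues", "CanopyMask", function(x, ...) x@values)
#' @rdname accessors
setMethod("gridRole", "ElevationGrid", function(x) x@role)
#' @rdname accessors
setMethod("indexName", "ValueGrid", function(x) x@indexName)
#' @rdname accessors
setMethod("maskThreshold", "CanopyMask", function(x) x@threshold)
#' @rdname accessors
setMethod("nPlots", "PlotSet", function(x) sum(x@meta$role == "plot"))
#' @rdname accessors
setMethod("plotIds", "PlotSet", function(x) x@meta$plot_id[x@meta$role == "plot"])
#' @rdname accessors
setMethod("plotPolygon", "PlotSet", function(x, id) {
  i <- match(id, x@meta$plot_id)
  if (is.na(i)) stop("no plot with plot_id '", id, "'")
  x@polygons[[i]]
})
#' @rdname accessors
setMethod("plotMeta", "PlotSet", function(x) x@meta)
#' @rdname accessors
setMethod("modelCoefficients", "AGBMModel", function(x) x@coefficients)
#' @rdname accessors
setMethod("modelIntercept", "AGBMModel", function(x) x@intercept)
#' @rdname accessors
setMethod("modelDivisor", "AGBMModel", function(x) x@divisor)

setMethod("show", "GeoTransform", function(object) {
  cat(sprintf("GeoTransform: origin (E %.3f, N %.3f), pixel %.4g m, north-up\n",
              object@originE, object@originN, object@pixelSize))
})

setMethod("show", "BandStack", function(object) {
  d <- dim(object@bands[[1]])
  cat(sprintf("BandStack: %d x %d pixels, bands %s\n", d[1], d[2],
              paste(names(object@bands), collapse = "/")))
  cat(sprintf("  pixel %.4g m, %d nodata pixel(s)\n",
              object@transform@pixelSize, sum(object@nodata)))
})

setMethod("show", "ElevationGrid", function(object) {
  d <- dim(object@values)
  v <- object@values[!object@nodata]
  rng <- if (length(v)) sprintf("[%.3f, %.3f] m", min(v), max(v)) else "(empty)"
  cat(sprintf("ElevationGrid (%s): %d x %d pixels, range %s, pixel %.4g m\n",
              object@role, d[1], d[2], rng, object@transform@pixelSize))
})

setMethod("show", "ValueGrid", function(object) {
  d <- dim(object@values)
  v <- object@values[!object@nodata]
  rng <- if (length(v)) sprintf("[%.3f, %.3f]", min(v), max(v)) else "(empty)"
  cat(sprintf("ValueGrid (%s): %d x %d pixels, range %s\n",
              object@indexName, d[1], d[2], rng))
})

setMethod("show", "CanopyMask", function(object) {
  cat(sprintf("CanopyMask: %d canopy / %d pixels (threshold %.3g m AGL)\n",
              sum(object@values), length(object@values), object@threshold))
})

setMethod("show", "PlotSet", function(object) {
  m <- object@meta
  cat(sprintf("PlotSet: %d plot(s), %d entry(ies), %d auxiliary feature(s)\n",
              sum(m$role == "plot"), length(unique(m$entry[m$role == "plot"])),
              sum(m$role != "plot")))
})

setMethod("show", "AGBMModel", function(object) {
  cat("AGBMModel (standardized linear biomass estimator)\n")
  cat(sprintf("  AGBM_Est = (sum(coef_i * x_i) + %.4g) / %.4g\n",
              object@intercept, object@divisor))
  for (f in object@featureNames)
    cat(sprintf("  %-10s %+0.4g\n", f, object@coefficients[[f]]))
})

setMethod("show", "LeafTypeModel", function(object) {
  cat(sprintf("LeafTypeModel: green > %.4g -> %s, else %s (training accuracy %.1f%%)\n",
              object@threshold, object@upperClass, object@lowerClass,
              100 * object@accuracy))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: GSD %.4g m, reflectance noise %.3g, elev noise %.3g m, quantum %.3g m\n",
              object@gsd, object@noiseSd, object@elevNoiseSd, object@elevQuantum))
})
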