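# Raster, vector and table I/O. Rasters are stored as ESRI ASCII grids
# (plain text, one file per band, full double precision); a five-band stack
# is a JSON sidecar naming its per-band grid files. Plot layers are GeoJSON;
# tables are headered CSV. All coordinates are projected easting/northing in
# metres.

.NODATA <- -99999

# ---- ESRI ASCII grid (single band) ------------------------------------------

.writeAsciiGrid <- function(values, nodata, transform, path) {
  nr <- nrow(values); nc <- ncol(values)
  ps <- transform@pixelSize
  v <- values
  v[nodata] <- .NODATA
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.17g", transform@originE),
    sprintf("yllcorner %.17g", transform@originN - nr * ps),
    sprintf("cellsize %.17g", ps),
    sprintf("NODATA_value %d", .NODATA)), con)
  for (r in seq_len(nr))
    writeLines(paste(sprintf("%.17g", v[r, ]), collapse = " "), con)
  path
}

.readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  missing <- setdiff(need, names(hdr))
  if (length(missing))
    stop("raster ", path, " is missing geotransform header field(s): ",
         paste(missing, collapse = ", "))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[seq.int(i, length(lines))], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("raster ", path, " declares ", nr * nc, " cells but contains ",
         length(vals))
  values <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  ndv <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else .NODATA
  nodata <- values == ndv
  values[nodata] <- NA_real_
  tr <- GeoTransform(originE = hdr$xllcorner,
                     originN = hdr$yllcorner + nr * hdr$cellsize,
                     pixelSize = hdr$cellsize)
  list(values = values, nodata = nodata, transform = tr)
}

# ---- elevation grids ---------------------------------------------------------

#' Read and write elevation rasters
#'
#' Elevation surfaces are stored as single ESRI ASCII grids. The grid role
#' (DSM / DTM / CSM) is recorded in the filename-independent \code{role}
#' argument on read and is the caller's statement of what the surface is.
#' Round trips are lossless: values are written at full double precision.
#'
#' @param grid an \linkS4class{ElevationGrid}.
#' @param path file path (.asc).
#' @param role role to assign on read: "DSM", "DTM" or "CSM".
#' @return \code{writeElevation}: the path, invisibly.
#'   \code{readElevation}: an \linkS4class{ElevationGrid}.
#' @export
writeElevation <- function(grid, path) {
  stopifnot(is(grid, "ElevationGrid"))
  .writeAsciiGrid(grid@values, grid@nodata, grid@transform, path)
  invisible(path)
}

#' @rdname writeElevation
#' @export
readElevation <- function(path, role = "DSM") {
  g <- .readAsciiGrid(path)
  v <- g$values
  v[g$nodata] <- 0          # masked cells never enter arithmetic
  ElevationGrid(v, g$transform, role = role, nodata = g$nodata)
}

# ---- band stacks -------------------------------------------------------------

#' Read and write five-band reflectance stacks
#'
#' A stack is stored as one ESRI ASCII grid per band plus a JSON sidecar
#' (\code{<prefix>.json}) listing the band order and files. \code{path} is
#' the sidecar path; band files live next to it.
#'
#' @param stack a \linkS4class{BandStack}.
#' @param path sidecar path (.json).
#' @return \code{writeBandStack}: the sidecar path, invisibly.
#'   \code{readBandStack}: a \linkS4class{BandStack}.
#' @export
writeBandStack <- function(stack, path) {
  stopifnot(is(stack, "BandStack"))
  prefix <- sub("\\.json$", "", path)
  files <- stats::setNames(paste0(basename(prefix), "_", .BAND_NAMES, ".asc"),
                           .BAND_NAMES)
  for (b in .BAND_NAMES)
    .writeAsciiGrid(stack@bands[[b]], stack@nodata, stack@transform,
                    file.path(dirname(path), files[[b]]))
  jsonlite::write_json(list(format = "uasPheno-bandstack", bands = as.list(files)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeBandStack
#' @export
readBandStack <- function(path) {
  if (!grepl("\\.json$", path)) {
    # a bare raster is a single band, not a stack
    stop("expected 5 bands (", paste(.BAND_NAMES, collapse = ", "),
         ") via a stack sidecar (.json); got a single raster file: ", path)
  }
  side <- jsonlite::read_json(path)
  got <- names(side$bands)
  if (!identical(sort(got), sort(.BAND_NAMES)))
    stop("expected 5 bands named ", paste(.BAND_NAMES, collapse = ", "),
         "; sidecar lists ", length(got), ": ", paste(got, collapse = ", "))
  grids <- lapply(.BAND_NAMES, function(b)
    .readAsciiGrid(file.path(dirname(path), side$bands[[b]])))
  trs <- lapply(grids, `[[`, "transform")
  for (g in trs[-1])
    if (!isTRUE(all.equal(g, trs[[1]])))
      stop("band grids disagree on geotransform")
  nodata <- Reduce(`|`, lapply(grids, `[[`, "nodata"))
  bands <- lapply(grids, function(g) { v <- g$values; v[g$nodata] <- 0; v })
  names(bands) <- .BAND_NAMES
  BandStack(bands, trs[[1]], nodata)
}

# ---- plot layers (GeoJSON) ---------------------------------------------------

#' Read and write plot polygon layers as GeoJSON
#'
#' Each feature is a Polygon with properties \code{plot_id}, \code{entry},
#' \code{replicate} and \code{role} ("plot" for trial plots, "panel" for the
#' radiometric reference panel). Coordinates are easting/northing in metres.
#' Duplicate plot_ids and self-intersecting polygons are rejected on read.
#'
#' @param plots a \linkS4class{PlotSet}.
#' @param path file path (.geojson).
#' @return \code{writePlots}: the path, invisibly. \code{readPlots}: a
#'   \linkS4class{PlotSet}.
#' @export
writePlots <- function(plots, path) {
  stopifnot(is(plots, "PlotSet"))
  m <- plots@meta
  feats <- lapply(seq_len(nrow(m)), function(i) {
    ring <- .closeRing(plots@polygons[[i]])
    list(type = "Feature",
         properties = list(plot_id = m$plot_id[i], entry = m$entry[i],
                           replicate = m$replicate[i], role = m$role[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) ring[k, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePlots
#' @export
readPlots <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  polys <- list(); meta <- list()
  for (f in gj$features) {
    pr <- f$properties
    if (is.null(pr$plot_id)) stop("feature without required property plot_id")
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(v) as.numeric(unlist(v))))
    polys[[length(polys) + 1L]] <- ring
    meta[[length(meta) + 1L]] <- data.frame(
      plot_id = as.character(pr$plot_id),
      entry = if (is.null(pr$entry)) NA_character_ else as.character(pr$entry),
      replicate = if (is.null(pr$replicate)) NA_integer_
                  else suppressWarnings(as.integer(pr$replicate)),
      role = if (is.null(pr$role)) "plot" else as.character(pr$role),
      stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  dup <- unique(meta$plot_id[duplicated(meta$plot_id)])
  if (length(dup))
    stop("duplicate plot_id in ", path, ": ", paste(dup, collapse = ", "))
  PlotSet(polys, meta)
}

# ---- tables ------------------------------------------------------------------

#' Read and write headered CSV tables against a schema
#'
#' The schema names the required columns and which of them are numeric;
#' unknown columns are preserved as character. Missing required columns are
#' rejected naming the column.
#'
#' @param path file path.
#' @param schema list with elements \code{required} (character),
#'   \code{numeric} and \code{logical} (character, columns coerced to those
#'   types).
#' @param table a data.frame.
#' @return \code{readTable}: a data.frame. \code{writeTable}: the path,
#'   invisibly.
#' @export
readTable <- function(path, schema = list(required = character(0),
                                          numeric = character(0),
                                          logical = character(0))) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing <- setdiff(schema$required, names(tab))
  if (length(missing))
    stop("table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (cn in intersect(schema$numeric, names(tab)))
    tab[[cn]] <- as.numeric(replace(tab[[cn]], tab[[cn]] %in% c("", "NA"), NA))
  for (cn in intersect(schema$logical, names(tab)))
    tab[[cn]] <- as.logical(tab[[cn]])
  tab
}

#' @rdname readTable
#' @export
writeTable <- function(table, path) {
  utils::write.csv(.formatFull(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Format numerics at full precision so CSV round trips are value-exact.
.formatFull <- function(tab) {
  for (cn in names(tab))
    if (is.numeric(tab[[cn]]) && !is.integer(tab[[cn]])) {
      v <- tab[[cn]]
      tab[[cn]] <- ifelse(is.na(v), "NA", sprintf("%.17g", v))
    }
  tab
}
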