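# Zonal statistics, the multi-timepoint feature table, accumulated degree
# days, and trait-feature correlation reports.

#' Zonal statistics of a grid over one polygon
#'
#' Sum, mean and contributing-pixel count of a grid over the pixels whose
#' centers fall inside the polygon, excluding nodata pixels and -- when a
#' canopy mask is supplied -- pixels outside the canopy (soil masking). An
#' empty intersection is not an error: it yields n = 0, sum = 0 and NA mean.
#'
#' @param grid a \linkS4class{ValueGrid} or \linkS4class{ElevationGrid}.
#' @param polygon n x 2 coordinate matrix.
#' @param mask optional \linkS4class{CanopyMask} restricting the statistics
#'   to canopy pixels.
#' @return list with elements sum, mean (NA when n = 0) and n.
#' @export
zonalStats <- function(grid, polygon, mask = NULL) {
  .zonalCore(grid@values, grid@nodata, grid@transform, polygon, mask)
}

.zonalCore <- function(vals, nodata, tr, polygon, mask = NULL) {
  px <- .polygonPixels(tr, dim(vals), polygon)
  if (nrow(px) == 0) return(list(sum = 0, mean = NA_real_, n = 0L))
  idx <- cbind(px[, "row"], px[, "col"])
  ok <- !nodata[idx]
  if (!is.null(mask)) ok <- ok & mask@values[idx]
  v <- vals[idx][ok]
  n <- length(v)
  list(sum = if (n) sum(v) else 0,
       mean = if (n) sum(v) / n else NA_real_,
       n = n)
}

#' Assemble the per-plot, per-timepoint feature table
#'
#' For each scene (one per ADD timepoint, panel-corrected band stack plus
#' crop surface model) computes the canopy mask, the four index grids, and
#' per plot: GRVI/NDVI/NDRE sums and means, the NIRv sum, CH_uas, CC and PV.
#' Vegetation-index statistics are soil-masked (restricted to canopy pixels)
#' by default; \code{maskVI = FALSE} reproduces the unmasked early-season
#' behaviour where bright soil dilutes the indices.
#'
#' @param scenes named list keyed by ADD; each element a list with elements
#'   \code{stack} (\linkS4class{BandStack}, reflectance) and \code{csm}
#'   (\linkS4class{ElevationGrid}, role CSM).
#' @param plots a \linkS4class{PlotSet}.
#' @param maskVI apply the canopy (soil) mask to VI statistics (default
#'   TRUE).
#' @param canopyThreshold segmentation threshold, m AGL.
#' @param nirvVariant "paper" or "badgley".
#' @param chStat CH statistic, see \code{\link{plotCanopyMetrics}}.
#' @return data.frame keyed (plot_id, add) with columns GRVI_sum, GRVI_mean,
#'   NDVI_sum, NDVI_mean, NDRE_sum, NDRE_mean, NIRv, CH_uas, CC, PV, plus
#'   G_mean (canopy-mean green reflectance, feeding leaf-type
#'   classification) and n_vi_pixels; attribute \code{vi_masked} records the
#'   provenance flag.
#' @export
buildFeatureTable <- function(scenes, plots, maskVI = TRUE,
                              canopyThreshold = 0.15,
                              nirvVariant = "paper", chStat = "mean") {
  adds <- names(scenes)
  if (anyDuplicated(adds))
    stop("duplicate ADD timepoint(s) in scenes: ",
         paste(unique(adds[duplicated(adds)]), collapse = ", "))
  m <- plotMeta(plots)
  keep <- which(m$role == "plot")
  rows <- list()
  for (addKey in adds) {
    sc <- scenes[[addKey]]
    grids <- list(GRVI = computeVI(sc$stack, "GRVI"),
                  NDVI = computeVI(sc$stack, "NDVI"),
                  NDRE = computeVI(sc$stack, "NDRE"),
                  NIRv = computeNIRv(sc$stack, nirvVariant))
    cmask <- segmentCanopy(sc$csm, canopyThreshold)
    metrics <- plotCanopyMetrics(sc$csm, cmask, plots, chStat = chStat)
    viMask <- if (maskVI) cmask else NULL
    for (i in keep) {
      poly <- plots@polygons[[i]]
      zs <- lapply(grids, zonalStats, polygon = poly, mask = viMask)
      zg <- .zonalCore(sc$stack@bands[["G"]], sc$stack@nodata,
                       sc$stack@transform, poly, cmask)
      mt <- metrics[metrics$plot_id == m$plot_id[i], ]
      rows[[length(rows) + 1L]] <- data.frame(
        plot_id = m$plot_id[i], add = as.numeric(addKey),
        GRVI_sum = zs$GRVI$sum, GRVI_mean = zs$GRVI$mean,
        NDVI_sum = zs$NDVI$sum, NDVI_mean = zs$NDVI$mean,
        NDRE_sum = zs$NDRE$sum, NDRE_mean = zs$NDRE$mean,
        NIRv = zs$NIRv$sum,
        CH_uas = mt$ch_uas, CC = mt$cc, PV = mt$pv,
        G_mean = zg$mean,
        n_vi_pixels = zs$GRVI$n,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "vi_masked") <- maskVI
  tab
}

#' Accumulated degree days at a 0 degree C base
#'
#' ADD(d) is the cumulative sum over days from the start date through d of
#' max(daily mean temperature - base, 0).
#'
#' @param dates Date vector, consecutive daily.
#' @param dailyMeanTemp daily mean temperatures, degrees C.
#' @param startDate accumulation start (must be in \code{dates}).
#' @param base base temperature, degrees C (default 0).
#' @return data.frame with columns date, daily_mean_temp, add (rows from
#'   startDate onward).
#' @export
computeADD <- function(dates, dailyMeanTemp, startDate, base = 0) {
  dates <- as.Date(dates)
  if (length(dates) != length(dailyMeanTemp))
    stop("dates and dailyMeanTemp lengths differ")
  if (any(as.numeric(diff(dates)) != 1))
    stop("dates must be consecutive daily")
  startDate <- as.Date(startDate)
  i0 <- match(startDate, dates)
  if (is.na(i0)) stop("startDate ", format(startDate),
                      " lies outside the temperature series")
  idx <- seq.int(i0, length(dates))
  contrib <- pmax(dailyMeanTemp[idx] - base, 0)
  data.frame(date = dates[idx], daily_mean_temp = dailyMeanTemp[idx],
             add = cumsum(contrib))
}

.starsFor <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                         ifelse(p < 0.05, "*", ""))))
}

# Pearson r with two-sided p via the t distribution (n - 2 df); returns NA r
# on zero variance.
.pearsonCell <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Trait-feature Pearson correlation report
#'
#' Correlates image features against ground-truth traits, either after
#' averaging replicate plots per entry (\code{"by_entry_mean"}, the winter
#' protocol) or plot by plot (\code{"by_plot"}, the spring protocol, used
#' when replicates are not measured on the same day). Cells are Pearson r
#' with two-sided p-values and significance stars at the 0.05 / 0.01 / 0.001
#' levels; zero-variance cells are flagged NA.
#'
#' @param features feature table (one ADD), keyed by plot_id.
#' @param truth data.frame keyed by plot_id with trait columns (and entry
#'   for the entry-mean protocol).
#' @param featureCols,traitCols column names to correlate.
#' @param grouping "by_entry_mean" or "by_plot".
#' @param plots \linkS4class{PlotSet} supplying the plot -> entry map when
#'   \code{truth} lacks an entry column.
#' @return data.frame of class "uasCorrelationReport" in long form: feature,
#'   trait, r, p, stars, n.
#' @export
correlateTraits <- function(features, truth, featureCols, traitCols,
                            grouping = c("by_entry_mean", "by_plot"),
                            plots = NULL) {
  grouping <- match.arg(grouping)
  dat <- merge(features, truth, by = "plot_id",
               suffixes = c("", ".truth"))
  if (grouping == "by_entry_mean") {
    if (is.null(dat$entry)) {
      if (is.null(plots)) stop("entry column or plots required for by_entry_mean")
      m <- plotMeta(plots)
      dat$entry <- m$entry[match(dat$plot_id, m$plot_id)]
    }
    num <- unique(c(featureCols, traitCols))
    dat <- stats::aggregate(dat[num], by = list(entry = dat$entry),
                            FUN = mean, na.rm = TRUE)
  }
  if (nrow(dat) < 3)
    stop("fewer than 3 units after grouping; cannot correlate")
  out <- list()
  for (f in featureCols) for (tcol in traitCols) {
    cell <- .pearsonCell(dat[[f]], dat[[tcol]])
    out[[length(out) + 1L]] <- data.frame(
      feature = f, trait = tcol, r = cell$r, p = cell$p,
      stars = .starsFor(cell$p), n = cell$n, stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  class(rep) <- c("uasCorrelationReport", "data.frame")
  rep
}
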