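# Synthetic trial generator: randomized-complete-block layouts, per-plot
# ground truth over accumulated degree days (ADD), and rasterized scenes
# (five-band reflectance + DSM) with known truth, so every downstream stage
# can be tested against what was simulated.

#' Default canopy growth parameters
#'
#' Canopy height and cover follow a unimodal beta-shaped curve over ADD:
#' they rise to a peak near flowering and decline toward physiological
#' maturity. The peak defaults to 1268 ADD (flowering in the winter trials)
#' on a season spanning 0--2200 ADD.
#'
#' @param peakAdd ADD at which the curve peaks (default 1268).
#' @param seasonEnd ADD at which the curve returns to zero (default 2200).
#' @param shape concentration of the beta-shaped curve (larger = narrower).
#' @param maxHeightMean,maxHeightSd per-plot peak canopy height distribution, m.
#' @param maxCoverMean,maxCoverSd per-plot peak cover fraction distribution
#'   (truncated to (0, 0.99]).
#' @return a named list of growth parameters.
#' @export
growthParams <- function(peakAdd = 1268, seasonEnd = 2200, shape = 6,
                         maxHeightMean = 0.7, maxHeightSd = 0.08,
                         maxCoverMean = 0.85, maxCoverSd = 0.06) {
  list(peakAdd = peakAdd, seasonEnd = seasonEnd, shape = shape,
       maxHeightMean = maxHeightMean, maxHeightSd = maxHeightSd,
       maxCoverMean = maxCoverMean, maxCoverSd = maxCoverSd)
}

#' Default linear AGBM link
#'
#' True per-plot above-ground biomass (kg fresh weight) is a linear function
#' of latent canopy state -- cover fraction (the driver of the
#' vegetation-index sums and canopy coverage) and height x cover (the driver
#' of plot volume) -- plus Gaussian noise.
#'
#' @param intercept kg.
#' @param coefCover kg per unit cover fraction.
#' @param coefHeightCover kg per (m x cover) unit.
#' @param noiseSd residual SD, kg.
#' @return a named list.
#' @export
agbmLink <- function(intercept = 2, coefCover = 4, coefHeightCover = 8,
                     noiseSd = 0.3) {
  list(intercept = intercept, coefCover = coefCover,
       coefHeightCover = coefHeightCover, noiseSd = noiseSd)
}

# Unimodal beta-shaped curve in [0, 1] with mode at peak, zero at 0 and end.
.growthCurve <- function(add, peak, end, shape) {
  x <- pmin(pmax(add / end, 0), 1)
  px <- peak / end
  a <- 1 + shape * px
  b <- 1 + shape * (1 - px)
  v <- x^(a - 1) * (1 - x)^(b - 1)
  vmax <- px^(a - 1) * (1 - px)^(b - 1)
  v / vmax
}

#' Generate a randomized-complete-block trial layout
#'
#' Lays out \code{nEntries * nReps} rectangular plots: each replicate is one
#' block (a west-east row of plots), blocks are stacked northward, and the
#' entry order within each block is an independently seeded random
#' permutation. Plot polygons are axis-aligned, non-overlapping, separated
#' by \code{alley} metres.
#'
#' @param nEntries number of entries (genotypes), >= 1.
#' @param nReps number of replicates (blocks), >= 1.
#' @param plotWidth,plotLength plot dimensions in m (default 1.5 x 5.0).
#' @param alley alley width between adjacent plots and blocks, m.
#' @param origin numeric length-2, easting/northing of the trial's southwest
#'   corner (m).
#' @param seed integer seed for the entry randomization.
#' @return a \linkS4class{PlotSet} whose meta has one row per plot with
#'   plot_id, entry, replicate.
#' @export
generateTrialLayout <- function(nEntries, nReps, plotWidth = 1.5,
                                plotLength = 5.0, alley = 0.5,
                                origin = c(0, 0), seed = 1) {
  for (nm in c("nEntries", "nReps", "plotWidth", "plotLength")) {
    v <- get(nm)
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      stop(nm, " must be a single positive value")
  }
  if (alley < 0) stop("alley must be >= 0")
  nEntries <- as.integer(nEntries); nReps <- as.integer(nReps)
  entries <- sprintf("E%02d", seq_len(nEntries))
  polys <- list(); meta <- list()
  k <- 0L
  for (rep in seq_len(nReps)) {
    order <- withSeed(deriveSeed(seed, paste0("layout-block-", rep)),
                      sample.int(nEntries))
    n0 <- origin[2] + (rep - 1) * (plotLength + alley)
    for (pos in seq_len(nEntries)) {
      e0 <- origin[1] + (pos - 1) * (plotWidth + alley)
      k <- k + 1L
      polys[[k]] <- cbind(c(e0, e0 + plotWidth, e0 + plotWidth, e0, e0),
                          c(n0, n0, n0 + plotLength, n0 + plotLength, n0))
      meta[[k]] <- data.frame(plot_id = sprintf("P%03d", k),
                              entry = entries[order[pos]],
                              replicate = rep, role = "plot",
                              stringsAsFactors = FALSE)
    }
  }
  PlotSet(polys, do.call(rbind, meta))
}

#' Generate per-plot ground truth over time
#'
#' For every plot and timepoint (in ADD) draws the latent canopy state the
#' rendered scenes will realize: mean canopy height, cover fraction, true
#' AGBM (linear in cover and height x cover plus noise), lodging status and
#' severity, leaf type, and per-band canopy/soil reflectance.
#'
#' Entry effects: peak height and cover are drawn per entry with small
#' replicate-level jitter, so replicates of an entry resemble each other.
#' Leaf type is an entry-level trait; the two types differ in mean green
#' canopy reflectance. A seeded subset of \code{round(lodgingFraction * n)}
#' plots is lodged: at timepoints after the growth peak their height is
#' multiplied by their lodging ratio (canopy height / total plant length, 1
#' = fully erect) and their cover is spread upward accordingly.
#'
#' @param layout a \linkS4class{PlotSet}.
#' @param timepoints strictly increasing ADD values.
#' @param growth list from \code{\link{growthParams}}.
#' @param link list from \code{\link{agbmLink}}.
#' @param lodgingFraction fraction of plots lodged, in [0, 1].
#' @param probAf probability an entry has normal (Af) leaves (else
#'   semi-leafless, af).
#' @param seed integer seed.
#' @return a data.frame with one row per (plot_id, add): columns plot_id,
#'   entry, replicate, add, height_m, cover, agbm, lodged, lodging_ratio,
#'   leaf_type, refl_B..refl_NIR (canopy), soil_B..soil_NIR.
#' @export
generateTruth <- function(layout, timepoints, growth = growthParams(),
                          link = agbmLink(), lodgingFraction = 0.15,
                          probAf = 0.5, seed = 1) {
  if (length(timepoints) == 0) stop("timepoints must be a non-empty vector")
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  if (lodgingFraction < 0 || lodgingFraction > 1)
    stop("lodgingFraction must lie in [0, 1]")
  m <- plotMeta(layout)
  m <- m[m$role == "plot", , drop = FALSE]
  n <- nrow(m)
  entries <- sort(unique(m$entry))

  # entry-level genetics
  ent <- withSeed(deriveSeed(seed, "truth-entries"), {
    data.frame(entry = entries,
               hmax = pmax(0.2, stats::rnorm(length(entries),
                                             growth$maxHeightMean,
                                             growth$maxHeightSd)),
               cmax = pmin(0.99, pmax(0.3, stats::rnorm(length(entries),
                                                        growth$maxCoverMean,
                                                        growth$maxCoverSd))),
               leaf_type = ifelse(stats::runif(length(entries)) < probAf,
                                  "Af", "af"),
               stringsAsFactors = FALSE)
  })

  # plot-level realization
  pl <- withSeed(deriveSeed(seed, "truth-plots"), {
    i <- match(m$entry, ent$entry)
    lodged_idx <- sample.int(n, size = round(lodgingFraction * n))
    lodged <- seq_len(n) %in% lodged_idx
    data.frame(plot_id = m$plot_id, entry = m$entry, replicate = m$replicate,
               hmax = pmax(0.15, ent$hmax[i] + stats::rnorm(n, 0, 0.02)),
               cmax = pmin(0.97, pmax(0.2, ent$cmax[i] + stats::rnorm(n, 0, 0.02))),
               leaf_type = ent$leaf_type[i],
               lodged = lodged,
               lodging_ratio = ifelse(lodged, stats::runif(n, 0.6, 0.85),
                                      stats::runif(n, 0.92, 1.0)),
               # per-plot canopy reflectance: leaf-type-dependent green
               refl_B = pmax(0.01, 0.04 + stats::rnorm(n, 0, 0.004)),
               refl_G = pmax(0.02, ifelse(ent$leaf_type[i] == "af", 0.135, 0.105) +
                               stats::rnorm(n, 0, 0.010)),
               refl_R = pmax(0.01, 0.06 + stats::rnorm(n, 0, 0.005)),
               refl_RE = pmax(0.05, 0.30 + stats::rnorm(n, 0, 0.015)),
               refl_NIR = pmax(0.10, 0.50 + stats::rnorm(n, 0, 0.02)),
               stringsAsFactors = FALSE)
  })

  soil <- c(soil_B = 0.10, soil_G = 0.14, soil_R = 0.16, soil_RE = 0.20,
            soil_NIR = 0.25)

  rows <- list()
  for (tp in timepoints) {
    g <- .growthCurve(tp, growth$peakAdd, growth$seasonEnd, growth$shape)
    height <- pl$hmax * g
    cover <- pmin(0.99, pl$cmax * g^0.4)
    post_peak <- tp > growth$peakAdd
    if (post_peak) {
      # lodged canopies collapse in height but spread on the ground: cover
      # rebounds above the plot's peak cover instead of senescing
      height <- ifelse(pl$lodged, height * pl$lodging_ratio, height)
      cover <- ifelse(pl$lodged,
                      pl$cmax + (0.985 - pl$cmax) * (1 - pl$lodging_ratio),
                      cover)
    }
    eps <- withSeed(deriveSeed(seed, paste0("truth-agbm-", tp)),
                    stats::rnorm(n, 0, link$noiseSd))
    agbm <- link$intercept + link$coefCover * cover +
      link$coefHeightCover * height * cover + eps
    rows[[length(rows) + 1L]] <- data.frame(
      plot_id = pl$plot_id, entry = pl$entry, replicate = pl$replicate,
      add = tp, height_m = height, cover = cover, agbm = pmax(0, agbm),
      lodged = pl$lodged & post_peak, lodging_ratio = pl$lodging_ratio,
      leaf_type = pl$leaf_type,
      refl_B = pl$refl_B, refl_G = pl$refl_G, refl_R = pl$refl_R,
      refl_RE = pl$refl_RE, refl_NIR = pl$refl_NIR,
      soil_B = soil[["soil_B"]], soil_G = soil[["soil_G"]],
      soil_R = soil[["soil_R"]], soil_RE = soil[["soil_RE"]],
      soil_NIR = soil[["soil_NIR"]],
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  truth
}

# Scene extent (map coords) from layout + buffer.
.sceneExtent <- function(layout, buffer) {
  allv <- do.call(rbind, layout@polygons)
  c(emin = min(allv[, 1]) - buffer, emax = max(allv[, 1]) + buffer,
    nmin = min(allv[, 2]) - buffer, nmax = max(allv[, 2]) + buffer)
}

# Default panel: 0.5 m square in the buffer strip southwest of the plots.
.defaultPanel <- function(ext) {
  e0 <- ext[["emin"]] + 0.3; n0 <- ext[["nmin"]] + 0.3
  cbind(c(e0, e0 + 0.5, e0 + 0.5, e0, e0),
        c(n0, n0, n0 + 0.5, n0 + 0.5, n0))
}

#' Render a synthetic scene at one timepoint
#'
#' Rasterizes the truth into a five-band reflectance stack and a DSM.
#' Pixels whose centers fall inside a plot are canopy with probability equal
#' to the plot's cover fraction (independent Bernoulli per pixel, seeded);
#' canopy pixels take the plot's canopy reflectance and elevation = terrain +
#' canopy height, all other pixels take soil reflectance and terrain
#' elevation. The white-panel region takes the panel reflectance in every
#' band. Additive per-band Gaussian noise at \code{noiseSd} and elevation
#' noise at \code{elevNoiseSd} are applied, reflectances are clamped at zero,
#' multiplied by the per-band sensor gain, and the DSM is quantized to
#' \code{elevQuantum}. Terrain is the smooth planar surface of the spec.
#'
#' @param truth data.frame from \code{\link{generateTruth}}.
#' @param layout the \linkS4class{PlotSet} the truth was generated for.
#' @param spec a \linkS4class{SceneSpec}.
#' @param timepoint one ADD value present in \code{truth$add}.
#' @param seed integer seed (per-scene sub-streams are derived from it and
#'   the timepoint).
#' @return list with elements \code{stack} (\linkS4class{BandStack}),
#'   \code{dsm} (\linkS4class{ElevationGrid}), \code{panel} (panel polygon
#'   matrix) and \code{canopyDraw} (logical matrix of realized canopy
#'   pixels).
#' @export
renderScene <- function(truth, layout, spec = SceneSpec(), timepoint,
                        seed = 1) {
  tt <- truth[truth$add == timepoint, , drop = FALSE]
  if (nrow(tt) == 0)
    stop("timepoint ", timepoint, " not present in truth")
  ext <- .sceneExtent(layout, spec@buffer)
  gsd <- spec@gsd
  nc <- as.integer(ceiling((ext[["emax"]] - ext[["emin"]]) / gsd - 1e-9))
  nr <- as.integer(ceiling((ext[["nmax"]] - ext[["nmin"]]) / gsd - 1e-9))
  tr <- GeoTransform(originE = ext[["emin"]],
                     originN = ext[["nmin"]] + nr * gsd, pixelSize = gsd)
  panel <- if (nrow(spec@panelRegion)) spec@panelRegion else .defaultPanel(ext)

  # terrain on pixel centers
  colE <- tr@originE + (seq_len(nc) - 0.5) * gsd
  rowN <- tr@originN - (seq_len(nr) - 0.5) * gsd
  terrain <- spec@terrainBase +
    outer(rep(1, nr), (colE - ext[["emin"]])) * spec@terrainSlopeE +
    outer((rowN - ext[["nmin"]]), rep(1, nc)) * spec@terrainSlopeN

  soil <- as.numeric(tt[1, c("soil_B", "soil_G", "soil_R", "soil_RE", "soil_NIR")])
  bands <- lapply(seq_along(.BAND_NAMES), function(b)
    matrix(soil[b], nr, nc))
  names(bands) <- .BAND_NAMES
  dsm <- terrain
  canopyDraw <- matrix(FALSE, nr, nc)

  sseed <- deriveSeed(seed, paste0("render-", timepoint))
  withSeed(sseed, {
    m <- plotMeta(layout)
    for (i in which(m$role == "plot")) {
      pid <- m$plot_id[i]
      row <- tt[tt$plot_id == pid, , drop = FALSE]
      if (nrow(row) == 0) next
      px <- .polygonPixels(tr, c(nr, nc), layout@polygons[[i]])
      if (nrow(px) == 0)
        stop("GSD ", gsd, " m is too coarse: plot ", pid,
             " contains zero pixels")
      idx <- cbind(px[, "row"], px[, "col"])
      canopy <- stats::runif(nrow(px)) < row$cover
      canopyDraw[idx[canopy, , drop = FALSE]] <- TRUE
      refl <- as.numeric(row[1, c("refl_B", "refl_G", "refl_R", "refl_RE",
                                  "refl_NIR")])
      for (b in seq_along(.BAND_NAMES)) {
        vb <- bands[[b]]
        vb[idx[canopy, , drop = FALSE]] <- refl[b]
        bands[[b]] <- vb
      }
      dsm[idx[canopy, , drop = FALSE]] <-
        dsm[idx[canopy, , drop = FALSE]] + row$height_m
    }
    # white reference panel overrides reflectance (it sits on the ground)
    ppx <- .polygonPixels(tr, c(nr, nc), panel)
    if (nrow(ppx)) {
      pidx <- cbind(ppx[, "row"], ppx[, "col"])
      for (b in seq_along(.BAND_NAMES)) {
        vb <- bands[[b]]
        vb[pidx] <- spec@panelReflectance
        bands[[b]] <- vb
      }
    }
    # sensor noise and gains
    for (b in seq_along(.BAND_NAMES)) {
      vb <- bands[[b]]
      if (spec@noiseSd > 0)
        vb <- vb + matrix(stats::rnorm(nr * nc, 0, spec@noiseSd), nr, nc)
      bands[[b]] <- pmax(vb, 0) * spec@bandGain[[b]]
    }
    if (spec@elevNoiseSd > 0)
      dsm <- dsm + matrix(stats::rnorm(nr * nc, 0, spec@elevNoiseSd), nr, nc)
  })
  dsm <- round(dsm / spec@elevQuantum) * spec@elevQuantum

  list(stack = BandStack(bands, tr),
       dsm = ElevationGrid(dsm, tr, role = "DSM"),
       panel = panel, canopyDraw = canopyDraw)
}

#' Generate synthetic GCP displacement pairs
#'
#' Draws \code{n} ground-control-point locations and displaces them with
#' independent Gaussian errors per axis, feeding the georeferencing QC
#' metrics.
#'
#' @param n number of GCPs, >= 1.
#' @param horizontalSd per-axis (easting and northing) displacement SD, m.
#' @param verticalSd elevation displacement SD, m.
#' @param extent numeric length-2: GCPs are spread uniformly over a square
#'   of this easting/northing size (m).
#' @param seed integer seed.
#' @return data.frame with columns id, E_true, N_true, Z_true, E_obs, N_obs,
#'   Z_obs.
#' @export
generateGcpErrors <- function(n, horizontalSd, verticalSd,
                              extent = c(100, 100), seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (horizontalSd < 0) stop("horizontalSd must be >= 0")
  if (verticalSd < 0) stop("verticalSd must be >= 0")
  withSeed(deriveSeed(seed, "gcp"), {
    et <- stats::runif(n, 0, extent[1])
    nt <- stats::runif(n, 0, extent[2])
    zt <- stats::runif(n, 95, 105)
    data.frame(id = sprintf("GCP%02d", seq_len(n)),
               E_true = et, N_true = nt, Z_true = zt,
               E_obs = et + stats::rnorm(n, 0, horizontalSd),
               N_obs = nt + stats::rnorm(n, 0, horizontalSd),
               Z_obs = zt + stats::rnorm(n, 0, verticalSd),
               stringsAsFactors = FALSE)
  })
}
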