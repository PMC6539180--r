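# Fixture builders: tiny stacks, grids and trials constructed in code.

bandNamesAll <- c("B", "G", "R", "RE", "NIR")

# Constant-valued 5-band stack.
makeFlatStack <- function(vals = c(B = 0.05, G = 0.5, R = 0.25, RE = 0.3,
                                   NIR = 0.5),
                          nr = 8, nc = 8, pixelSize = 0.5,
                          originE = 0, originN = nr * pixelSize) {
  tr <- GeoTransform(originE, originN, pixelSize)
  BandStack(lapply(as.list(vals[bandNamesAll]),
                   function(v) matrix(v, nr, nc)), tr)
}

# Random-valued stack (reflectances in (0.01, 1)).
makeRandomStack <- function(nr = 16, nc = 16, pixelSize = 0.5, seed = 42) {
  withr::with_seed(seed, {
    tr <- GeoTransform(0, nr * pixelSize, pixelSize)
    bands <- lapply(bandNamesAll,
                    function(b) matrix(runif(nr * nc, 0.01, 1), nr, nc))
    names(bands) <- bandNamesAll
    BandStack(bands, tr)
  })
}

makeElevation <- function(values, pixelSize = 0.5, role = "DSM") {
  ElevationGrid(values, GeoTransform(0, nrow(values) * pixelSize, pixelSize),
                role = role)
}

# Axis-aligned rectangle polygon.
rectPoly <- function(e0, n0, w, h) {
  cbind(c(e0, e0 + w, e0 + w, e0, e0), c(n0, n0, n0 + h, n0 + h, n0))
}

# Brute-force zonal oracle: loops over every pixel, tests its center.
# Contributions are collected column-major (columns outer, rows inner) so the
# accumulation order matches a column-major traversal before summing.
zonalOracle <- function(values, nodata, transform, polygon, maskVals = NULL) {
  keep <- numeric(0)
  for (cc in seq_len(ncol(values))) for (r in seq_len(nrow(values))) {
    ctr <- pixelToMap(transform, r, cc)
    if (pointInPolygon(ctr$e, ctr$n, polygon) && !nodata[r, cc] &&
        (is.null(maskVals) || maskVals[r, cc]))
      keep <- c(keep, values[r, cc])
  }
  n <- length(keep)
  list(sum = if (n) sum(keep) else 0,
       mean = if (n) sum(keep) / n else NA_real_, n = n)
}

# Simulated feature table generated from a known standardized linear model.
lassoFixture <- function(n = 180, beta = c(GRVI_sum = 2.0, NDVI_sum = -0.8,
                                           NDRE_sum = 0.7, CC = 1.2),
                         intercept = 10, noiseSd = 0, seed = 31) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * length(beta)), n)
    colnames(x) <- names(beta)
    x <- scale(x)             # exact standardization of the design
    y <- as.numeric(x %*% beta) + intercept + rnorm(n, 0, noiseSd)
    feats <- data.frame(plot_id = sprintf("P%04d", seq_len(n)), x)
    list(features = feats,
         agbm = data.frame(plot_id = feats$plot_id, agbm = y),
         beta = beta, names = names(beta))
  })
}

# Brute-force normalized-difference oracle.
ndOracle <- function(a, b) {
  out <- matrix(NA_real_, nrow(a), ncol(a))
  for (r in seq_len(nrow(a))) for (cc in seq_len(ncol(a))) {
    den <- a[r, cc] + b[r, cc]
    if (den != 0) out[r, cc] <- (a[r, cc] - b[r, cc]) / den
  }
  out
}

# All-FALSE canopy mask on the same grid.
CanopyMaskZero <- function(csm) {
  segmentCanopy(csm, max(gridValues(csm), 0) + 1)
}

# Small rendered trial for recovery tests.
smallTrial <- function(nEntries = 3, nReps = 2, timepoints = 1268,
                       noiseSd = 0, elevNoiseSd = 0, gsd = 0.05,
                       lodgingFraction = 0, seed = 5, slope = 0.01) {
  layout <- generateTrialLayout(nEntries, nReps, seed = seed)
  truth <- generateTruth(layout, timepoints,
                         lodgingFraction = lodgingFraction, seed = seed)
  spec <- SceneSpec(gsd = gsd, noiseSd = noiseSd, elevNoiseSd = elevNoiseSd,
                    terrainSlopeE = slope)
  list(layout = layout, truth = truth, spec = spec, seed = seed)
}
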