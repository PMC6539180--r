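# Synthetic trial generator: layouts, truth dynamics, rendering, GCPs.

test_that("RCBD layout has the right plots, areas and disjoint polygons", {
  layout <- generateTrialLayout(20, 3, plotWidth = 1.5, plotLength = 5.0,
                                seed = 2)
  expect_equal(nPlots(layout), 60)
  areas <- vapply(seq_len(60), function(i)
    abs(uasPheno:::.ringArea(uasPheno:::.closeRing(layout@polygons[[i]]))),
    numeric(1))
  expect_equal(areas, rep(7.5, 60))
  m <- plotMeta(layout)
  expect_equal(nrow(unique(m[c("entry", "replicate")])), 60)

  # pairwise interior disjointness, brute-force vertex-in-other oracle
  small <- generateTrialLayout(5, 3, alley = 0.5, seed = 9)
  polys <- small@polygons
  for (i in seq_along(polys)) for (j in seq_along(polys)) {
    if (i >= j) next
    ri <- uasPheno:::.closeRing(polys[[i]])
    # sample interior points of i (centroid + vertices shrunk toward it)
    # and assert none fall inside polygon j
    ctr <- colMeans(ri[-nrow(ri), ])
    shrunk <- t(apply(ri[-nrow(ri), ], 1,
                      function(v) ctr + (v - ctr) * (1 - 1e-9)))
    pts <- rbind(ctr, shrunk)
    expect_false(any(pointInPolygon(pts[, 1], pts[, 2], polys[[j]])))
  }
})

test_that("degenerate one-plot design sits at the origin", {
  layout <- generateTrialLayout(1, 1, origin = c(10, 20), seed = 1)
  expect_equal(nPlots(layout), 1)
  expect_equal(min(layout@polygons[[1]][, 1]), 10)
  expect_equal(min(layout@polygons[[1]][, 2]), 20)
})

test_that("invalid layout dimensions are rejected naming the field", {
  expect_error(generateTrialLayout(0, 3), "nEntries")
  expect_error(generateTrialLayout(3, 3, plotWidth = -1), "plotWidth")
})

test_that("growth peaks near the configured flowering timepoint", {
  layout <- generateTrialLayout(6, 2, seed = 4)
  truth <- generateTruth(layout, c(365, 1268, 1948), seed = 4)
  hm <- tapply(truth$height_m, truth$add, mean)
  expect_gt(hm[["1268"]], hm[["365"]])
  expect_gt(hm[["1268"]], hm[["1948"]])
})

test_that("noiseless AGBM link is exactly linear in the latent features", {
  layout <- generateTrialLayout(5, 2, seed = 6)
  link <- agbmLink(noiseSd = 0)
  truth <- generateTruth(layout, c(784, 1268), link = link, seed = 6)
  expected <- link$intercept + link$coefCover * truth$cover +
    link$coefHeightCover * truth$height_m * truth$cover
  expect_equal(truth$agbm, expected, tolerance = 1e-12)
})

test_that("the seeded lodged subset has exactly the requested size", {
  layout <- generateTrialLayout(20, 5, seed = 8)   # 100 plots
  truth <- generateTruth(layout, c(1268, 1725), lodgingFraction = 0.3,
                         seed = 8)
  late <- truth[truth$add == 1725, ]
  expect_equal(sum(late$lodged), 30)
  expect_equal(sum(truth$lodged[truth$add == 1268]), 0)  # pre-peak: none yet
})

test_that("lodged plots are strictly shorter and better covered than their
           erect counterfactual at late timepoints", {
  layout <- generateTrialLayout(10, 3, seed = 12)
  lodged <- generateTruth(layout, c(1268, 1725), lodgingFraction = 0.4,
                          seed = 12)
  erect <- generateTruth(layout, c(1268, 1725), lodgingFraction = 0,
                         seed = 12)
  l <- lodged[lodged$add == 1725 & lodged$lodged, ]
  e <- erect[erect$add == 1725, ]
  e <- e[match(l$plot_id, e$plot_id), ]
  expect_true(all(l$height_m < e$height_m))
  expect_true(all(l$cover > e$cover))
  expect_true(all(l$lodging_ratio > 0 & l$lodging_ratio <= 1))
})

test_that("noiseless full-cover rendering is exact: DSM, NDVI, panel", {
  layout <- generateTrialLayout(1, 1, seed = 3)
  truth <- generateTruth(layout, 1268, lodgingFraction = 0, seed = 3)
  truth$cover <- 1
  truth$height_m <- 0.5
  truth$refl_NIR <- 0.50
  truth$refl_R <- 0.10
  spec <- SceneSpec(gsd = 0.1, noiseSd = 0, elevNoiseSd = 0,
                    terrainBase = 100, terrainSlopeE = 0, terrainSlopeN = 0)
  sc <- renderScene(truth, layout, spec, 1268, seed = 3)
  tr <- gridTransform(sc$dsm)
  px <- uasPheno:::.polygonPixels(tr, dim(gridValues(sc$dsm)),
                                  layout@polygons[[1]])
  idx <- cbind(px[, "row"], px[, "col"])
  expect_true(all(gridValues(sc$dsm)[idx] == 100.5))
  ndvi <- computeVI(sc$stack, "NDVI")
  expect_equal(unique(gridValues(ndvi)[idx]), (0.5 - 0.1) / (0.5 + 0.1),
               tolerance = 1e-12)
  # panel pixels are exactly the panel reflectance in all five bands
  ppx <- uasPheno:::.polygonPixels(tr, dim(gridValues(sc$dsm)), sc$panel)
  pidx <- cbind(ppx[, "row"], ppx[, "col"])
  for (b in bandNamesAll)
    expect_true(all(getBand(sc$stack, b)[pidx] == 0.99))
})

test_that("rendering rejects a GSD too coarse to resolve a plot", {
  layout <- generateTrialLayout(1, 1, plotWidth = 0.5, plotLength = 0.5,
                                seed = 1)
  truth <- generateTruth(layout, 1268, seed = 1)
  expect_error(renderScene(truth, layout, SceneSpec(gsd = 5), 1268, seed = 1),
               "P001")
})

test_that("scene generation is bit-reproducible for a fixed seed", {
  tr <- smallTrial(2, 1, noiseSd = 0.02, elevNoiseSd = 0.01, seed = 21)
  a <- renderScene(tr$truth, tr$layout, tr$spec, 1268, seed = 21)
  b <- renderScene(tr$truth, tr$layout, tr$spec, 1268, seed = 21)
  expect_identical(gridValues(a$dsm), gridValues(b$dsm))
  for (bn in bandNamesAll)
    expect_identical(getBand(a$stack, bn), getBand(b$stack, bn))
})

test_that("in-plot canopy fraction converges to the cover fraction", {
  layout <- generateTrialLayout(1, 1, seed = 30)
  truth <- generateTruth(layout, 1268, seed = 30)
  truth$cover <- 0.6
  spec <- SceneSpec(gsd = 0.05, noiseSd = 0, elevNoiseSd = 0)
  fracs <- vapply(1:8, function(s) {
    sc <- renderScene(truth, layout, spec, 1268, seed = s)
    tr <- gridTransform(sc$dsm)
    px <- uasPheno:::.polygonPixels(tr, dim(sc$canopyDraw),
                                    layout@polygons[[1]])
    mean(sc$canopyDraw[cbind(px[, "row"], px[, "col"])])
  }, numeric(1))
  npix <- 30 * 100  # 1.5 m x 5.0 m at 0.05 m
  se <- sqrt(0.6 * 0.4 / (npix * length(fracs)))
  expect_lt(abs(mean(fracs) - 0.6), 3 * se)
})

test_that("GCP displacement generator honors its contracts", {
  g0 <- generateGcpErrors(10, 0, 0, seed = 1)
  expect_equal(nrow(g0), 10)
  expect_equal(g0$E_obs, g0$E_true)
  expect_equal(g0$Z_obs, g0$Z_true)
  expect_error(generateGcpErrors(10, -1, 0), "horizontalSd")
  # Monte-Carlo: RMS horizontal displacement approaches sd * sqrt(2)
  g <- generateGcpErrors(10000, 2, 0.1, seed = 7)
  expect_lt(abs(computeHPE(g) / (2 * sqrt(2)) - 1), 0.03)
})
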