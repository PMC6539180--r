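# Zonal statistics, feature table assembly, ADD, correlation reports.

test_that("zonal statistics match constants and flag empty intersections", {
  g <- ValueGrid(matrix(0.4, 20, 20), GeoTransform(0, 10, 0.5), "NDVI")
  poly <- rectPoly(1, 1, 5, 5)   # 10 x 10 = 100 pixels
  zs <- zonalStats(g, poly)
  expect_equal(zs$n, 100)
  expect_equal(zs$sum, 100 * 0.4)
  expect_equal(zs$mean, 0.4)
  # empty intersection: n = 0, sum = 0, mean flagged
  empty <- zonalStats(g, rectPoly(100, 100, 1, 1))
  expect_equal(empty$n, 0)
  expect_equal(empty$sum, 0)
  expect_true(is.na(empty$mean))
  # mask excluding everything behaves like the empty case
  csm <- ElevationGrid(matrix(0, 20, 20), GeoTransform(0, 10, 0.5),
                       role = "CSM")
  masked <- zonalStats(g, poly, mask = segmentCanopy(csm, 0.15))
  expect_equal(masked$n, 0)
  expect_true(is.na(masked$mean))
})

test_that("zonal statistics equal the brute-force pixel loop on random
           polygon/raster pairs", {
  withr::with_seed(99, {
    for (k in 1:10) {
      nr <- sample(8:16, 1); nc <- sample(8:16, 1)
      ps <- runif(1, 0.2, 1)
      tr <- GeoTransform(runif(1, -5, 5), nr * ps + runif(1, -5, 5), ps)
      vals <- matrix(rnorm(nr * nc), nr, nc)
      nodata <- matrix(runif(nr * nc) < 0.1, nr, nc)
      g <- ValueGrid(vals, tr, "NIRv", nodata)
      # random triangle or rectangle inside the raster
      if (k %% 2 == 0) {
        poly <- rectPoly(tr@originE + runif(1, 0, nc * ps / 2),
                         tr@originN - nr * ps + runif(1, 0, nr * ps / 2),
                         runif(1, ps, nc * ps / 2), runif(1, ps, nr * ps / 2))
      } else {
        poly <- cbind(tr@originE + runif(3, 0, nc * ps),
                      tr@originN - runif(3, 0, nr * ps))
      }
      got <- zonalStats(g, poly)
      want <- zonalOracle(vals, nodata, tr, poly)
      expect_identical(got$n, want$n)
      expect_identical(got$sum, want$sum)
      expect_identical(got$mean, want$mean)
    }
  })
})

test_that("zonal sums are additive over a partition of a polygon", {
  withr::with_seed(7, {
    g <- ValueGrid(matrix(rnorm(400), 20, 20), GeoTransform(0, 10, 0.5),
                   "NIRv")
    whole <- rectPoly(0.9, 1.3, 6, 4)
    left <- rectPoly(0.9, 1.3, 3.1, 4)     # split at e = 4.0
    right <- rectPoly(4.0, 1.3, 2.9, 4)
    zw <- zonalStats(g, whole)
    zl <- zonalStats(g, left); zr <- zonalStats(g, right)
    expect_equal(zl$n + zr$n, zw$n)
    expect_equal(zl$sum + zr$sum, zw$sum, tolerance = 1e-12)
  })
})

test_that("the soil mask never increases n or the sum of a nonnegative grid", {
  withr::with_seed(13, {
    vals <- matrix(runif(400), 20, 20)
    g <- ValueGrid(vals, GeoTransform(0, 10, 0.5), "NIRv")
    z <- matrix(runif(400, 0, 0.4), 20, 20)
    mask <- segmentCanopy(ElevationGrid(z, GeoTransform(0, 10, 0.5),
                                        role = "CSM"), 0.15)
    poly <- rectPoly(1, 1, 7, 6)
    un <- zonalStats(g, poly)
    ma <- zonalStats(g, poly, mask = mask)
    expect_lte(ma$n, un$n)
    expect_lte(ma$sum, un$sum)
  })
})

test_that("feature table has one row per plot per timepoint and is
           deterministic", {
  tr <- smallTrial(3, 2, timepoints = c(784, 1268), noiseSd = 0.01,
                   elevNoiseSd = 0.003, seed = 19)
  scenes <- list()
  for (tp in c(784, 1268)) {
    sc <- renderScene(tr$truth, tr$layout, tr$spec, tp, seed = 19)
    dtm <- buildDTM(sc$dsm, plots = tr$layout)
    scenes[[as.character(tp)]] <- list(stack = sc$stack,
                                       csm = computeCSM(sc$dsm, dtm))
  }
  ft <- buildFeatureTable(scenes, tr$layout)
  expect_equal(nrow(ft), 6 * 2)
  expect_equal(anyDuplicated(ft[c("plot_id", "add")]), 0L)
  expect_true(all(c("GRVI_sum", "NDVI_mean", "NIRv", "CH_uas", "CC", "PV")
                  %in% names(ft)))
  # mean = sum / n wherever pixels contributed
  ok <- ft$n_vi_pixels > 0
  expect_equal(ft$GRVI_mean[ok], ft$GRVI_sum[ok] / ft$n_vi_pixels[ok],
               tolerance = 1e-12)
  ft2 <- buildFeatureTable(scenes, tr$layout)
  expect_identical(ft, ft2)
  expect_error(buildFeatureTable(c(scenes, scenes["784"]), tr$layout),
               "duplicate ADD")
})

test_that("accumulated degree days: closed-form sums and clamping", {
  dates <- seq(as.Date("2018-05-01"), by = "day", length.out = 30)
  add <- computeADD(dates, rep(10, 30), startDate = dates[1])
  expect_equal(add$add[30], 300)
  expect_equal(add$add[1], 10)     # the start date contributes its own day
  # below-base days contribute nothing
  cold <- computeADD(dates, rep(-3, 30), startDate = dates[1])
  expect_true(all(cold$add == 0))
  one <- computeADD(dates, c(21.5, rep(0, 29)), startDate = dates[1])
  expect_equal(one$add[1], 21.5)
  expect_true(all(diff(add$add) >= 0))
  expect_error(computeADD(dates, rep(10, 30),
                          startDate = as.Date("2018-04-01")), "startDate")
})

test_that("correlation report: affine dependence, oracle equality, guards", {
  withr::with_seed(55, {
    feats <- data.frame(plot_id = sprintf("P%02d", 1:20),
                        GRVI_sum = runif(20, 100, 900))
    truth <- data.frame(plot_id = feats$plot_id,
                        agbm = 2 * feats$GRVI_sum + 5,
                        noisevar = rnorm(20),
                        const = 1)
    rep <- correlateTraits(feats, truth, "GRVI_sum",
                           c("agbm", "noisevar", "const"),
                           grouping = "by_plot")
    r1 <- rep[rep$trait == "agbm", ]
    expect_equal(r1$r, 1.0, tolerance = 1e-12)
    expect_equal(r1$stars, "***")
    # independent noise matches the reference implementation to 1e-12
    ct <- cor.test(feats$GRVI_sum, truth$noisevar)
    r2 <- rep[rep$trait == "noisevar", ]
    expect_equal(r2$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(r2$p, ct$p.value, tolerance = 1e-12)
    # zero-variance trait is flagged, not an error
    r3 <- rep[rep$trait == "const", ]
    expect_true(is.na(r3$r))
    expect_equal(r3$stars, "")
  })
  expect_error(correlateTraits(data.frame(plot_id = "a", x = 1),
                               data.frame(plot_id = "a", y = 1),
                               "x", "y", grouping = "by_plot"),
               "fewer than 3")
})

test_that("entry-mean grouping with one replicate equals plot-wise grouping", {
  withr::with_seed(77, {
    feats <- data.frame(plot_id = sprintf("P%02d", 1:12),
                        GRVI_sum = runif(12), PV = runif(12))
    truth <- data.frame(plot_id = feats$plot_id,
                        entry = sprintf("E%02d", 1:12),
                        agbm = rnorm(12))
    byPlot <- correlateTraits(feats, truth, c("GRVI_sum", "PV"), "agbm",
                              grouping = "by_plot")
    byEntry <- correlateTraits(feats, truth, c("GRVI_sum", "PV"), "agbm",
                               grouping = "by_entry_mean")
    expect_equal(byEntry$r, byPlot$r, tolerance = 1e-12)
    expect_equal(byEntry$p, byPlot$p, tolerance = 1e-12)
  })
})
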