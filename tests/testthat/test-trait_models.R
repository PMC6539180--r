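# Lodging scores, leaf-type classification, AGBM presets and Lasso fitting.

featRow <- function(plot_id, add, ch, cc) {
  data.frame(plot_id = plot_id, add = add, CH_uas = ch, CC = cc,
             stringsAsFactors = FALSE)
}

test_that("lodging score arithmetic matches its definition", {
  a <- featRow("P1", 1231, 0.5, 0.4)
  b <- featRow("P1", 1648, 0.5, 0.4)
  expect_equal(lodgingScore(a, b)$score, 0)
  b2 <- featRow("P1", 1648, 0.3, 0.6)
  expect_equal(lodgingScore(a, b2)$score, 0.2 * (-0.2))
  expect_equal(lodgingScore(a, b2, includeCC = FALSE)$score, 0.2)
  expect_error(lodgingScore(a, featRow("P2", 1648, 0.3, 0.6)), "plot ids")
  expect_error(lodgingScore(b2, a), "ADD1")
})

test_that("lodged synthetic plots score opposite in sign to erect plots", {
  tr <- smallTrial(8, 3, timepoints = c(1268, 1725), noiseSd = 0,
                   elevNoiseSd = 0, lodgingFraction = 0.4, seed = 23)
  scenes <- list()
  for (tp in c(1268, 1725)) {
    sc <- renderScene(tr$truth, tr$layout, tr$spec, tp, seed = 23)
    dtm <- buildDTM(sc$dsm, plots = tr$layout)
    scenes[[as.character(tp)]] <- list(stack = sc$stack,
                                       csm = computeCSM(sc$dsm, dtm))
  }
  ft <- buildFeatureTable(scenes, tr$layout)
  t1 <- ft[ft$add == 1268, ]; tk <- ft[ft$add == 1725, ]
  tk <- tk[match(t1$plot_id, tk$plot_id), ]
  sc <- lodgingScore(t1, tk)
  late <- tr$truth[tr$truth$add == 1725, ]
  lodged <- late$lodged[match(sc$plot_id, late$plot_id)]
  expect_true(all(sc$score[lodged] < 0))
  expect_true(all(sc$score[!lodged] > 0))
})

test_that("leaf-type threshold classifier handles the canonical regimes", {
  # perfectly separated classes
  g <- c(rnorm0 <- seq(0.08, 0.10, length.out = 10),
         seq(0.14, 0.16, length.out = 10))
  lab <- rep(c("Af", "af"), each = 10)
  m <- fitLeafType(g, lab)
  expect_equal(m@accuracy, 1.0)
  expect_gt(m@threshold, 0.10)
  expect_lt(m@threshold, 0.14)
  pred <- classifyLeafType(m, c(0.09, 0.15), c("Af", "af"))
  expect_equal(pred$labels, c("Af", "af"))
  expect_equal(pred$accuracy, 1.0)
  # two Gaussians 3 SD apart: accuracy at least 90%
  withr::with_seed(61, {
    g2 <- c(rnorm(100, 0.105, 0.01), rnorm(100, 0.135, 0.01))
    lab2 <- rep(c("Af", "af"), each = 100)
    m2 <- fitLeafType(g2, lab2)
    expect_gte(m2@accuracy, 0.90)
    # threshold lies between the class means
    expect_gt(m2@threshold, 0.105)
    expect_lt(m2@threshold, 0.135)
  })
  # degenerate all-equal input: majority-class accuracy
  m3 <- fitLeafType(rep(0.1, 10), c(rep("af", 7), rep("Af", 3)))
  expect_equal(m3@accuracy, 0.7)
  expect_error(fitLeafType(1:5, rep("af", 5)), "two classes")
})

test_that("leaf-type accuracy is invariant under monotone transforms", {
  withr::with_seed(62, {
    g <- c(rnorm(50, 0.105, 0.012), rnorm(50, 0.135, 0.012))
    lab <- rep(c("Af", "af"), each = 50)
    a1 <- fitLeafType(g, lab)@accuracy
    a2 <- fitLeafType(exp(5 * g), lab)@accuracy
    a3 <- fitLeafType(-1 / g, lab)@accuracy
    expect_equal(a2, a1)
    expect_equal(a3, a1)
  })
})

test_that("standardization is exact and reversible", {
  withr::with_seed(5, {
    tab <- data.frame(a = rnorm(40, 100, 12), b = runif(40), c = 1)
    std <- standardizeFeatures(tab, c("a", "b"))
    for (f in c("a", "b")) {
      expect_lt(abs(mean(std$table[[f]])), 1e-12)
      expect_equal(sd(std$table[[f]]), 1, tolerance = 1e-12)
      back <- std$table[[f]] * std$scales[[f]] + std$centers[[f]]
      expect_equal(back, tab[[f]], tolerance = 1e-12)
    }
    expect_error(standardizeFeatures(tab, "c"), "c")
  })
})

test_that("the frozen presets evaluate the printed equations", {
  w <- agbmPreset("winter_1268")
  zeros <- as.data.frame(as.list(setNames(rep(0, 4),
                                          w@featureNames)))
  expect_equal(applyAGBMModel(w, zeros, standardized = TRUE), 8.85 / 1.5e4)
  one <- zeros; one$GRVI_sum <- 1
  expect_equal(applyAGBMModel(w, one, standardized = TRUE),
               (1.56 + 8.85) / 1.5e4)
  s <- agbmPreset("spring_1231")
  zeros5 <- as.data.frame(as.list(setNames(rep(0, 5), s@featureNames)))
  expect_equal(applyAGBMModel(s, zeros5, standardized = TRUE), 87.83 / 1e3)
  expect_error(applyAGBMModel(w, zeros[-1], standardized = TRUE), "GRVI_sum")
})

test_that("AGBM models are affine: estimate of average = average of estimates", {
  withr::with_seed(9, {
    w <- agbmPreset("winter_1268")
    r1 <- as.data.frame(as.list(setNames(rnorm(4), w@featureNames)))
    r2 <- as.data.frame(as.list(setNames(rnorm(4), w@featureNames)))
    avg <- (r1 + r2) / 2
    expect_equal(applyAGBMModel(w, avg, standardized = TRUE),
                 mean(c(applyAGBMModel(w, r1, standardized = TRUE),
                        applyAGBMModel(w, r2, standardized = TRUE))),
                 tolerance = 1e-12)
  })
})

test_that("Lasso recovers a known model, shrinks null responses, and is
           deterministic", {
  fx <- lassoFixture(noiseSd = 0)
  fit <- fitLassoAGBM(fx$features, fx$agbm, fx$names, seed = 41)
  expect_true(all(abs(modelCoefficients(fit$model) - fx$beta) <=
                    0.05 * abs(fx$beta)))
  expect_gt(fit$validation_r, 0.999)

  # noise at 10% of the signal scale: validation still strong
  fxn <- lassoFixture(noiseSd = 0.1 * sqrt(sum(fx$beta^2)), seed = 32)
  fitn <- fitLassoAGBM(fxn$features, fxn$agbm, fxn$names, seed = 41)
  expect_gte(fitn$validation_r, 0.9)

  # pure-noise response: every coefficient shrunk essentially to zero
  fx0 <- lassoFixture(beta = c(GRVI_sum = 0, NDVI_sum = 0, NDRE_sum = 0,
                               CC = 0), noiseSd = 1, n = 300, seed = 33)
  fit0 <- fitLassoAGBM(fx0$features, fx0$agbm, fx0$names, seed = 41)
  expect_true(all(abs(modelCoefficients(fit0$model)) < 0.05))

  # determinism: identical inputs and seed give an identical model
  fitb <- fitLassoAGBM(fx$features, fx$agbm, fx$names, seed = 41)
  expect_identical(modelCoefficients(fit$model),
                   modelCoefficients(fitb$model))
  expect_identical(fit$lambda, fitb$lambda)

  expect_error(fitLassoAGBM(fx$features[1:5, ], fx$agbm[1:5, ], fx$names),
               "at least 10")
  expect_error(fitLassoAGBM(fx$features, fx$agbm, fx$names, trainFrac = 1.2),
               "trainFrac")
})

test_that("a vanishing penalty approaches the OLS fit on the training split", {
  fx <- lassoFixture(noiseSd = 0.3, seed = 35)
  std <- standardizeFeatures(merge(fx$features, fx$agbm, by = "plot_id"),
                             fx$names)
  n <- nrow(std$table)
  train <- uasPheno::deriveSeed(41, "lasso-split")
  idx <- withr::with_seed(train, sample.int(n, round(0.85 * n)))
  x <- as.matrix(std$table[fx$names])[idx, ]
  y <- std$table$agbm[idx]
  small <- glmnet::glmnet(x, y, alpha = 1, lambda = 1e-6,
                          standardize = FALSE)
  ols <- lm(y ~ x)
  expect_true(all(abs(as.numeric(small$beta) - coef(ols)[-1]) <=
                    0.01 * pmax(abs(coef(ols)[-1]), 1e-6)))
})

test_that("entry predictions equal a group-by average oracle", {
  withr::with_seed(71, {
    layout <- generateTrialLayout(20, 3, seed = 71)
    w <- agbmPreset("winter_1268")
    feats <- data.frame(plot_id = plotIds(layout),
                        matrix(rnorm(60 * 4), 60,
                               dimnames = list(NULL, w@featureNames)))
    ent <- predictEntries(w, feats, layout, standardized = TRUE)
    expect_equal(nrow(ent), 20)
    est <- applyAGBMModel(w, feats, standardized = TRUE)
    m <- plotMeta(layout)
    oracle <- tapply(est, m$entry[match(feats$plot_id, m$plot_id)], mean)
    expect_equal(ent$agbm_est, as.numeric(oracle[ent$entry]),
                 tolerance = 1e-12)
    expect_equal(ent$above_mean, ent$agbm_est > mean(ent$agbm_est))
    expect_error(predictEntries(w, feats[-1, ], layout, standardized = TRUE),
                 "P001")
  })
})

test_that("model JSON round trips, including NA standardization of presets", {
  d <- withr::local_tempdir()
  fx <- lassoFixture(noiseSd = 0.2, seed = 36)
  fit <- fitLassoAGBM(fx$features, fx$agbm, fx$names, seed = 41)
  p <- file.path(d, "model.json")
  writeAGBMModel(fit$model, p)
  back <- readAGBMModel(p)
  expect_equal(modelCoefficients(back), modelCoefficients(fit$model))
  expect_equal(back@centers, fit$model@centers)
  p2 <- file.path(d, "preset.json")
  writeAGBMModel(agbmPreset("winter_1268"), p2)
  back2 <- readAGBMModel(p2)
  expect_true(all(is.na(back2@centers)))
  expect_equal(modelCoefficients(back2),
               c(GRVI_sum = 1.56, NDVI_sum = -0.83, NDRE_sum = 0.75,
                 CC = -0.01))
})
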