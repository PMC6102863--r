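# Yield regression and averaged leave-one-out cross-validation.

test_that("OLS fit matches the closed-form oracle on small sets", {
  f <- fitLinearYield(c(0, 1, 2, 3), 2 * c(0, 1, 2, 3) + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1)
  expect_equal(f$rmse, 0)
  expect_equal(f$cv, 0)

  x <- c(1, 2, 3); y <- c(1, 2, 4)
  f <- fitLinearYield(x, y)
  o <- olsOracle(x, y)
  expect_equal(f$slope, o$slope, tolerance = 1e-12)
  expect_equal(f$intercept, o$intercept, tolerance = 1e-12)
  expect_equal(f$r2, o$r2, tolerance = 1e-12)
  # hand-derived exact values: slope 3/2, intercept -2/3, R2 = 27/28
  expect_equal(f$slope, 1.5, tolerance = 1e-12)
  expect_equal(f$intercept, -2/3, tolerance = 1e-12)
  expect_equal(f$r2, 27/28, tolerance = 1e-12)
  expect_equal(f$rmse, sqrt(o$ssres / 3), tolerance = 1e-12)
  expect_equal(f$cv, 100 * f$rmse / mean(y), tolerance = 1e-12)

  expect_error(fitLinearYield(c(1, 1, 1), c(1, 2, 3)),
               "degenerate predictor")
  expect_error(fitLinearYield(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fitLinearYield(c(1, 2, 3), c(-1, 0, 1)), "CV undefined")
})

test_that("noiseless synthetic tables return the generating coefficients", {
  cfg <- smallConfig(seed = 29L, yieldSigma = 0)
  sc <- synthesizeScene(cfg)
  pred <- viImage <- (sc$truth@plotReflectance[, 5] -
                        sc$truth@plotReflectance[, 3]) /
    (sc$truth@plotReflectance[, 5] + sc$truth@plotReflectance[, 3]) *
    sc$truth@plotAbundances[, "SS-LF"]
  f <- fitLinearYield(pred, sc$yields)
  expect_equal(f$slope, cfg@yieldSlope, tolerance = 1e-8)
  expect_equal(f$intercept, cfg@yieldIntercept, tolerance = 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-10)

  # noiseless LOOCV averages also equal the generating coefficients
  cv <- loocvYield(pred, sc$yields)
  expect_equal(cv@summary$slope, cfg@yieldSlope, tolerance = 1e-8)
  expect_equal(cv@summary$intercept, cfg@yieldIntercept, tolerance = 1e-8)
  expect_equal(cv@summary$rmse, 0, tolerance = 1e-8)
})

test_that("LOOCV on a K = 4 toy set matches exhaustive fold enumeration", {
  x <- c(0.1, 0.25, 0.4, 0.6)
  y <- c(1100, 1900, 2500, 3400)
  cv <- loocvYield(x, y, ids = sprintf("P%02d", 1:4))

  slopes <- intercepts <- r2s <- errs <- numeric(4)
  for (i in 1:4) {
    o <- olsOracle(x[-i], y[-i])
    slopes[i] <- o$slope; intercepts[i] <- o$intercept; r2s[i] <- o$r2
    errs[i] <- y[i] - (o$slope * x[i] + o$intercept)
  }
  expect_equal(cv@summary$slope, mean(slopes), tolerance = 1e-10)
  expect_equal(cv@summary$intercept, mean(intercepts), tolerance = 1e-10)
  expect_equal(cv@summary$r2, mean(r2s), tolerance = 1e-10)
  expect_equal(cv@summary$rmse, sqrt(mean(errs^2)), tolerance = 1e-10)
  expect_equal(cv@summary$cv, 100 * sqrt(mean(errs^2)) / mean(y),
               tolerance = 1e-10)
  expect_equal(cv@folds$error, errs, tolerance = 1e-10)
  expect_equal(cv@folds$held_out, sprintf("P%02d", 1:4))

  # self-consistency: summary RMSE recomputable from the emitted folds
  expect_equal(cv@summary$rmse, sqrt(mean(cv@folds$error^2)),
               tolerance = 1e-12)

  # perfect-fit fixed point: every fold identical, zero RMSE
  yl <- 5 * x + 2
  cvl <- loocvYield(x, yl)
  expect_equal(unique(round(cvl@folds$slope, 10)), 5)
  expect_equal(cvl@summary$rmse, 0, tolerance = 1e-10)

  # determinism and fold-failure naming
  expect_identical(loocvYield(x, y)@summary, loocvYield(x, y)@summary)
  expect_error(loocvYield(c(1, 1, 1, 2), y), "fold 4.*degenerate")
  expect_error(loocvYield(c(1, 2, 3), c(1, 2, 3)), "K >= 4")
})

test_that("R-squared of the generating predictor degrades monotonically with noise", {
  r2s <- vapply(c(0, 100, 300), function(sg) {
    cfg <- smallConfig(seed = 37L, yieldSigma = sg)
    sc <- synthesizeScene(cfg)
    pred <- (sc$truth@plotReflectance[, 5] - sc$truth@plotReflectance[, 3]) /
      (sc$truth@plotReflectance[, 5] + sc$truth@plotReflectance[, 3]) *
      sc$truth@plotAbundances[, "SS-LF"]
    fitLinearYield(pred, sc$yields)$r2
  }, numeric(1))
  expect_true(all(diff(r2s) <= 0))
  expect_equal(r2s[1], 1, tolerance = 1e-10)
})

test_that("evaluateAll ranks families, reports 40 fits and cross-validates the shortlist", {
  cfg <- smallConfig(seed = 41L)
  sc <- synthesizeScene(cfg)
  refl <- applyCalibration(sc$image, fitEmpiricalLine(sc$panels))
  am <- unmixImage(refl, sc$library)
  tab <- buildPlotTable(refl, am, sc$rois, sc$yields)
  rep <- evaluateAll(tab)

  expect_equal(nrow(rep$fits), 40L)
  expect_setequal(unique(rep$fits$family),
                  c("VI", "VIxFL", "VIxLEAF", "VIxSS"))
  expect_equal(nrow(rep$loocv), 4L)
  expect_s4_class(rep$loocvReports$NDVI, "CrossValReport")

  # yields were generated from NDVI x Abd_SS-LF: that family must beat
  # NDVI alone
  ndvi <- rep$fits[rep$fits$vi == "NDVI", ]
  expect_gt(ndvi$r2[ndvi$family == "VIxSS"], ndvi$r2[ndvi$family == "VI"])

  # negative control: shuffling yields collapses the fit
  set.seed(4242)
  tabS <- tab
  tabS$yield_kg_ha <- sample(tabS$yield_kg_ha)
  repS <- evaluateAll(tabS)
  expect_lt(max(repS$fits$r2[repS$fits$vi == "NDVI"]), 0.5)

  expect_error(evaluateAll(tab[, setdiff(names(tab), "ndvi")]),
               "missing column")
  tabNA <- tab; tabNA$yield_kg_ha[3] <- NA
  expect_error(evaluateAll(tabNA), "missing yields")
})
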