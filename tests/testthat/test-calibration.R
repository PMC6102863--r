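# Empirical-line calibration: per-band OLS over the panel readings and its
# application to DN imagery.

test_that("noiseless panels recover the true gain and bias to 1e-10", {
  cfg <- smallConfig(seed = 3L, noiseSigma = 0)
  sc <- synthesizeScene(cfg)
  m <- fitEmpiricalLine(sc$panels)
  expect_lt(max(abs(unname(gains(m)) - cfg@gains)), 1e-10)
  expect_lt(max(abs(unname(biases(m)) - cfg@biases)), 1e-10)
  expect_lt(max(m@rss), 1e-18)
})

test_that("two panels give the closed-form interpolating line", {
  panels <- data.frame(reflectance = rep(c(0.06, 1.00), each = 6),
                       band_nm = rep(rapemixBands, 2),
                       mean_DN = rep(c(100, 2000), each = 6))
  m <- fitEmpiricalLine(panels)
  G <- 0.94 / 1900
  expect_equal(unname(gains(m)), rep(G, 6), tolerance = 1e-12)
  expect_equal(unname(biases(m)), rep(0.06 - 100 * G, 6), tolerance = 1e-12)
})

test_that("the OLS fit matches independent oracles for noisy panels", {
  set.seed(71)
  dn <- c(120, 480, 960, 1990)
  refl <- c(0.06, 0.24, 0.48, 1.00) + rnorm(4, 0, 0.004)
  panels <- data.frame(reflectance = rep(refl, each = 6),
                       band_nm = rep(rapemixBands, 4),
                       mean_DN = rep(dn, each = 6))
  m <- fitEmpiricalLine(panels)

  # normal-equations oracle
  o <- olsOracle(dn, refl)
  expect_equal(unname(gains(m))[1], o$slope, tolerance = 1e-12)
  expect_equal(unname(biases(m))[1], o$intercept, tolerance = 1e-12)
  expect_equal(m@rss[1], o$ssres, tolerance = 1e-12)

  # brute-force zooming grid search over (G, B) reaches the same residual SS
  rssOf <- function(G, B) sum((refl - (B + G * dn))^2)
  Gc <- o$slope; Bc <- o$intercept
  wG <- abs(Gc); wB <- 0.05
  best <- Inf
  for (round in 1:4) {
    gr <- expand.grid(G = seq(Gc - wG, Gc + wG, length.out = 41),
                      B = seq(Bc - wB, Bc + wB, length.out = 41))
    v <- mapply(rssOf, gr$G, gr$B)
    i <- which.min(v)
    best <- v[i]; Gc <- gr$G[i]; Bc <- gr$B[i]
    wG <- wG / 10; wB <- wB / 10
  }
  expect_equal(m@rss[1], best, tolerance = 1e-6)
  expect_lte(m@rss[1], best + 1e-12)

  # lm() as a second, implementation-independent cross-check on all
  # panel subsets of size >= 2
  for (k in 2:4) {
    idx <- utils::combn(4, k)
    for (j in seq_len(ncol(idx))) {
      sub <- panels[panels$mean_DN %in% dn[idx[, j]], ]
      mj <- fitEmpiricalLine(sub)
      cf <- stats::coef(stats::lm(reflectance ~ mean_DN,
                                  data = sub[sub$band_nm == 490, ]))
      expect_equal(unname(biases(mj))[1], unname(cf[1]), tolerance = 1e-10)
      expect_equal(unname(gains(mj))[1], unname(cf[2]), tolerance = 1e-10)
    }
  }
})

test_that("degenerate panel sets are rejected with the band named", {
  panels <- data.frame(reflectance = rep(c(0.06, 0.24), each = 6),
                       band_nm = rep(rapemixBands, 2),
                       mean_DN = rep(c(500, 500), each = 6))
  expect_error(fitEmpiricalLine(panels), "rank-deficient.*490")
  one <- data.frame(reflectance = 0.06, band_nm = 490, mean_DN = 100)
  expect_error(fitEmpiricalLine(one), "insufficient panels.*490")
})

test_that("applyCalibration is the affine map of the fitted line", {
  m <- new("EmpiricalLineModel", gains = rep(5e-4, 6),
           biases = seq(0.01, 0.06, by = 0.01), rss = rep(0, 6),
           bandCenters = rapemixBands)
  zero <- SpectralImage(array(0, c(4, 5, 6)), unit = "DN")
  out <- applyCalibration(zero, m)
  expect_equal(imageUnit(out), "reflectance")
  for (b in 1:6)
    expect_true(all(imageData(out)[, , b] == m@biases[b]))   # DN = 0 -> B

  ident <- new("EmpiricalLineModel", gains = rep(1, 6), biases = rep(0, 6),
               rss = rep(0, 6), bandCenters = rapemixBands)
  set.seed(8)
  v <- array(runif(4 * 5 * 6), c(4, 5, 6))
  img <- SpectralImage(v, unit = "DN")
  expect_equal(imageData(applyCalibration(img, ident)), v)

  # linearity: calibrating a*DN1 + b*DN2 with zero bias is affine
  mz <- new("EmpiricalLineModel", gains = runif(6, 1e-4, 1e-3),
            biases = rep(0, 6), rss = rep(0, 6), bandCenters = rapemixBands)
  v2 <- array(runif(4 * 5 * 6), c(4, 5, 6))
  comb <- applyCalibration(SpectralImage(2 * v + 3 * v2, unit = "DN"), mz)
  sep <- 2 * imageData(applyCalibration(SpectralImage(v, unit = "DN"), mz)) +
         3 * imageData(applyCalibration(SpectralImage(v2, unit = "DN"), mz))
  expect_equal(imageData(comb), sep, tolerance = 1e-12)

  # already-calibrated input is an invalid state
  expect_error(applyCalibration(out, m), "already in 'reflectance'")
})

test_that("out-of-range reflectance passes through unclipped but counted", {
  m <- new("EmpiricalLineModel", gains = rep(1e-3, 6), biases = rep(-0.5, 6),
           rss = rep(0, 6), bandCenters = rapemixBands)
  img <- SpectralImage(array(c(0, 2000), c(1, 2, 6)), unit = "DN")
  out <- applyCalibration(img, m)
  expect_equal(imageData(out)[1, 1, 1], -0.5)    # negative, not clipped
  expect_equal(imageData(out)[1, 2, 1], 1.5)     # > 1, not clipped
  expect_equal(attr(out, "outOfRange"), 12L)
})

test_that("panel extraction uses the plain arithmetic mean over the rectangle", {
  v <- array(0, c(6, 8, 6))
  v[2:3, 2:5, ] <- rep(c(10, 20, 30, 40, 50, 60), each = 8)
  img <- SpectralImage(v, unit = "DN")
  rois <- data.frame(panel_id = "panel_01", reflectance = 0.06,
                     x0 = 1, y0 = 1, x1 = 5, y1 = 3)
  got <- extractPanelDN(img, rois)
  expect_equal(got$mean_DN, c(10, 20, 30, 40, 50, 60))
  expect_equal(nrow(got), 6L)
})
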