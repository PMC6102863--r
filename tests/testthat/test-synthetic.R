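# Synthetic scene generator: endmember library, abundance fields, rendering,
# yields.

test_that("default endmember library encodes the field-observed spectral relations", {
  lib <- defaultEndmemberLibrary()
  m <- spectra(lib)
  expect_identical(colnames(m), c("FL", "SE-LF", "SS-LF", "W-soil", "D-soil"))

  # flower blue reflectance 3% vs leaf 8%
  expect_equal(m["490", "FL"], 0.03)
  expect_equal(m["490", "SE-LF"], 0.08)
  expect_equal(m["490", "SS-LF"], 0.08)
  # flower above leaf in green, red and NIR
  for (b in c("550", "670", "800", "900")) {
    expect_gt(m[b, "FL"], m[b, "SE-LF"])
    expect_gt(m[b, "FL"], m[b, "SS-LF"])
  }
  # sessile leaf: lower green, slightly higher NIR than short-stalk leaf
  expect_lt(m["550", "SE-LF"], m["550", "SS-LF"])
  expect_gt(m["800", "SE-LF"], m["800", "SS-LF"])
  # wet soil below dry soil at every band
  expect_true(all(m[, "W-soil"] < m[, "D-soil"]))
  # all values in (0,1), full column rank
  expect_true(all(m > 0 & m < 1))
  expect_equal(qr(m)$rank, 5L)

  expect_error(defaultEndmemberLibrary(c(400, 500, 600, 700, 800, 900)),
               "unsupported bands")
})

test_that("abundance fields are simplex-valued, nitrogen-structured and deterministic", {
  cfg <- smallConfig(seed = 11L)
  ab <- generateAbundanceField(cfg)

  s <- rowSums(pixmat(ab))
  expect_lt(max(abs(s - 1)), 1e-12)
  expect_true(all(ab >= 0 & ab <= 1))

  # mean leaf abundance strictly higher in a high-N plot than a zero-N plot
  p0 <- cfg@plots[cfg@plots$n_rate == 0, ][1, ]
  p7 <- cfg@plots[cfg@plots$n_rate == 360, ][1, ]
  leaf <- function(p) mean(ab[(p$y0 + 1):p$y1, (p$x0 + 1):p$x1, 3])
  expect_gt(leaf(p7), leaf(p0))

  # group structure: mean short-stalk-leaf abundance non-decreasing with N
  rates <- sort(unique(cfg@plots$n_rate))
  groupSS <- vapply(rates, function(r) {
    ps <- cfg@plots[cfg@plots$n_rate == r, ]
    mean(vapply(seq_len(nrow(ps)), function(i) {
      p <- ps[i, ]
      mean(ab[(p$y0 + 1):p$y1, (p$x0 + 1):p$x1, 3])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(groupSS) >= 0))

  # ridge pixels are soil-dominated
  expect_gt(ab[1, cfg@width, 4] + ab[1, cfg@width, 5], 0.9)

  # determinism
  expect_identical(ab, generateAbundanceField(cfg))
})

test_that("rendering obeys the linear mixing model and inverts exactly without noise", {
  cfg <- smallConfig(seed = 5L, noiseSigma = 0)
  lib <- defaultEndmemberLibrary()
  ab <- generateAbundanceField(cfg)
  # plant a pure-flower pixel inside the first plot
  p <- cfg@plots[1, ]
  ab[p$y0 + 3, p$x0 + 3, ] <- c(1, 0, 0, 0, 0)
  sc <- renderScene(cfg, lib, ab)

  dn <- imageData(sc$image)
  refl <- dn
  for (b in 1:6) refl[, , b] <- dn[, , b] * cfg@gains[b] + cfg@biases[b]

  # pure-flower pixel reproduces the flower library row exactly
  expect_equal(refl[p$y0 + 3, p$x0 + 3, ], unname(spectra(lib)[, "FL"]),
               tolerance = 1e-12)

  # round-trip: calibrating with true G/B reproduces the mixture at every
  # non-panel pixel to 1e-10
  expected <- pixmat(ab) %*% t(spectra(lib))
  pan <- panelMask(cfg)
  expect_lt(max(abs(pixmat(refl)[!pan, ] - expected[!pan, ])), 1e-10)

  # panel mean DN strictly monotone in nominal reflectance (positive gains)
  for (b in rapemixBands) {
    sub <- sc$panels[sc$panels$band_nm == b, ]
    sub <- sub[order(sub$reflectance), ]
    expect_true(all(diff(sub$mean_DN) > 0))
  }

  # zero gain rejected at config level
  expect_error(sceneConfig(gains = c(0, rep(5e-4, 5))), "nonzero gains")
})

test_that("yield generation follows the configured linear model exactly", {
  lib <- defaultEndmemberLibrary()
  # a ground truth with a hand-chosen predictor: NDVI = 0.5, Abd_SS = 0.4
  refl <- matrix(c(0.05, 0.10, 0.20, 0.30, 0.60, 0.60), 1,
                 dimnames = list("P01", as.character(rapemixBands)))
  abd <- matrix(c(0.2, 0.2, 0.4, 0.1, 0.1), 1,
                dimnames = list("P01", endmemberNames(lib)))
  truth <- new("GroundTruth", abundances = array(0, c(1, 1, 5)),
               plotAbundances = abd, plotReflectance = refl,
               yields = numeric(0), gains = rep(1, 6), biases = rep(0, 6),
               library = lib)
  cfg <- smallConfig()
  cfg@plots <- cfg@plots[1, ]
  cfg@yieldSlope <- 8059.7
  cfg@yieldIntercept <- 204.22
  cfg@yieldSigma <- 0
  # NDVI = (0.6 - 0.2) / 0.8 = 0.5; predictor = 0.5 * 0.4 = 0.2
  expect_equal(unname(generateYields(cfg, truth)), 8059.7 * 0.2 + 204.22,
               tolerance = 1e-10)
  expect_equal(unname(generateYields(cfg, truth)), 1816.16,
               tolerance = 1e-10)

  # predictor zero -> intercept
  abd0 <- abd; abd0[1, "SS-LF"] <- 0
  truth0 <- truth; truth0@plotAbundances <- abd0
  expect_equal(unname(generateYields(cfg, truth0)), 204.22, tolerance = 1e-10)

  # unknown predictor
  cfgBad <- cfg; cfgBad@yieldAbundance <- "STEM"
  expect_error(generateYields(cfgBad, truth), "unknown predictor")
  cfgBad2 <- cfg; cfgBad2@yieldVI <- "NDWI"
  expect_error(generateYields(cfgBad2, truth), "unknown index")
})

test_that("default scene yields stay in the stated range and the scene is reproducible", {
  sc <- synthesizeScene(sceneConfig())
  expect_length(sc$yields, 24L)
  expect_true(all(sc$yields >= 800 & sc$yields <= 3800))

  sc2 <- synthesizeScene(sceneConfig())
  expect_identical(imageData(sc$image), imageData(sc2$image))
  expect_identical(sc$panels, sc2$panels)
  expect_identical(sc$yields, sc2$yields)
})

test_that("scene config validity rejects malformed worlds", {
  expect_error(sceneConfig(noiseSigma = -0.1), "sigmas must be >= 0")
  cfg <- smallConfig()
  bad <- cfg@plots
  bad$x1[2] <- bad$x0[1] + 30L   # force overlap with plot 1
  bad$x0[2] <- bad$x0[1]
  bad$y0[2] <- bad$y0[1]
  bad$y1[2] <- bad$y1[1]
  expect_error({cfg@plots <- bad; validObject(cfg)}, "overlap")
})
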