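#' Configure a synthetic rapeseed scene
#'
#' Builds a \linkS4class{SceneConfig} describing a fully ground-truthed
#' synthetic field trial. The default world mirrors the experimental design
#' the pipeline targets: eight nitrogen rates (0, 45, 90, 135, 180, 225, 270,
#' 360 kg/ha), each replicated on three plots randomly placed in a 6 x 4 plot
#' grid, 24 plots of 100 x 40 px in a 480 x 320 px image (a desk-scale
#' stand-in for ~30,000-pixel field plots), four calibration panels at 6, 24,
#' 48 and 100 percent reflectance rendered through the same sensor model, and
#' yields generated linearly from NDVI times short-stalk-leaf abundance with
#' Gaussian noise so that noiseless yields span roughly 1000--3500 kg/ha.
#'
#' @param width,height image size in pixels (columns, rows).
#' @param gains,biases true per-band sensor gain (reflectance per DN) and bias
#'   (reflectance) used to render DN; ground truth for calibration recovery.
#' @param noiseSigma additive Gaussian reflectance noise sd (default 0.005).
#' @param nRates the eight nitrogen rates (kg/ha).
#' @param replicates plots per rate.
#' @param plotWidth,plotHeight plot rectangle size in pixels.
#' @param pixelConcentration Dirichlet concentration total for per-pixel
#'   abundance draws (larger = more homogeneous plots).
#' @param plotConcentration Dirichlet concentration total for plot-level mean
#'   jitter around the nitrogen-group mean.
#' @param yieldVI,yieldAbundance predictor of the yield model: a vegetation
#'   index name and an abundance combination ("none", "FL", "SE-LF+SS-LF" or
#'   "SS-LF").
#' @param yieldSlope,yieldIntercept,yieldSigma yield model parameters (kg/ha).
#' @param quantize round DN to 10-bit integers (default FALSE so round-trip
#'   oracles are exact).
#' @param seed master seed; every stochastic stage derives its stream from it.
#' @return A validated \linkS4class{SceneConfig}.
#' @export
sceneConfig <- function(width = 480L, height = 320L,
                        gains = c(5.2, 5.0, 4.8, 4.6, 4.4, 4.2) * 1e-4,
                        biases = c(0.012, 0.010, 0.010, 0.008, 0.006, 0.005),
                        noiseSigma = 0.005,
                        nRates = c(0, 45, 90, 135, 180, 225, 270, 360),
                        replicates = 3L,
                        plotWidth = 100L, plotHeight = 40L,
                        pixelConcentration = 60,
                        plotConcentration = 300,
                        yieldVI = "NDVI", yieldAbundance = "SS-LF",
                        yieldSlope = 6500, yieldIntercept = 1000,
                        yieldSigma = 150,
                        quantize = FALSE, seed = 42L) {
  nPlots <- length(nRates) * replicates
  nCols <- 4L
  nRows <- as.integer(ceiling(nPlots / nCols))
  gapX <- max(1L, (width - nCols * plotWidth) %/% (nCols + 1L))
  gapY <- max(1L, (height - 10L - nRows * plotHeight) %/% (nRows + 1L))
  if (nCols * plotWidth + (nCols + 1L) * 1L > width ||
      nRows * plotHeight + 10L > height)
    stopf("image too small for %d plots of %d x %d px", nPlots,
          plotWidth, plotHeight)
  # randomised assignment of rates to plot positions, deterministic in seed
  rates <- withSeed(seed, sample(rep(nRates, each = replicates)))
  idx <- seq_len(nPlots) - 1L
  col <- idx %% nCols
  row <- idx %/% nCols
  x0 <- gapX + col * (plotWidth + gapX)
  y0 <- 10L + gapY + row * (plotHeight + gapY)
  plots <- data.frame(
    plot_id = sprintf("P%02d", seq_len(nPlots)),
    n_rate = rates,
    x0 = as.integer(x0), y0 = as.integer(y0),
    x1 = as.integer(x0 + plotWidth), y1 = as.integer(y0 + plotHeight))
  # four panels in the top margin (rows 0..9)
  px0 <- as.integer(20 + (0:3) * 30)
  panels <- data.frame(
    panel_id = sprintf("panel_%02d", 1:4),
    reflectance = c(0.06, 0.24, 0.48, 1.00),
    x0 = px0, y0 = 1L, x1 = px0 + 20L, y1 = 9L)
  new("SceneConfig", width = as.integer(width), height = as.integer(height),
      bandCenters = rapemixBands, gains = gains, biases = biases,
      noiseSigma = noiseSigma, plots = plots, panels = panels,
      pixelConcentration = pixelConcentration,
      plotConcentration = plotConcentration,
      yieldVI = yieldVI, yieldAbundance = yieldAbundance,
      yieldSlope = yieldSlope, yieldIntercept = yieldIntercept,
      yieldSigma = yieldSigma, quantize = quantize, seed = as.integer(seed))
}

# Mean abundance (FL, SE-LF, SS-LF, W-soil, D-soil) for nitrogen group g
# (0-based). Short-stalk-leaf abundance rises linearly with nitrogen, the
# sessile leaf tracks it at 30%, flower cover is flat (flowering canopies
# look alike from above), soil takes the remainder split 40/60 wet/dry.
.groupMeanAbundance <- function(g, nGroups = 8L) {
  ss <- 0.12 + 0.47 * g / (nGroups - 1L)
  se <- 0.30 * ss
  fl <- 0.20
  soil <- 1 - fl - ss - se
  c(fl, se, ss, 0.4 * soil, 0.6 * soil)
}

# Separable Gaussian smoothing of one channel with edge renormalisation;
# identical weights per channel so a unit-sum field stays unit-sum.
.smooth2d <- function(m, kern) {
  r <- (length(kern) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc); wt <- matrix(0, nr, nc)
  for (dy in -r:r) {
    for (dx in -r:r) {
      w <- kern[dy + r + 1L] * kern[dx + r + 1L]
      sr <- max(1L, 1L - dy):min(nr, nr - dy)
      sc <- max(1L, 1L - dx):min(nc, nc - dx)
      acc[sr, sc] <- acc[sr, sc] + w * m[sr + dy, sc + dx]
      wt[sr, sc] <- wt[sr, sc] + w
    }
  }
  acc / wt
}

#' Generate the per-pixel true abundance field
#'
#' Inside each plot, pixel abundance five-vectors are drawn from a Dirichlet
#' distribution whose mean shifts with the plot's nitrogen group (higher
#' nitrogen, higher leaf abundance), spatially smoothed with a small Gaussian
#' kernel and re-projected onto the simplex, reproducing the within-plot
#' homogeneity / between-plot heterogeneity of real abundance images. Ridge
#' pixels between plots are soil-dominated by construction (vegetation share
#' fixed at 0.03). Deterministic given the config seed.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @param seed RNG seed; defaults to the config seed.
#' @return rows x cols x 5 abundance array (every pixel sums to 1).
#' @export
generateAbundanceField <- function(config, seed = config@seed) {
  validObject(config)
  h <- config@height; w <- config@width
  nem <- 5L
  rates <- sort(unique(config@plots$n_rate))
  kern <- stats::dnorm(-2:2, sd = 1)
  kern <- kern / sum(kern)
  withSeed(seed, {
    arr <- array(0, dim = c(h, w, nem))
    # ridges: 97% soil split stochastically wet/dry, 1% each vegetation class
    soil <- rdirichlet(h * w, 50 * c(0.4, 0.6))
    arr[, , 1L] <- 0.01
    arr[, , 2L] <- 0.01
    arr[, , 3L] <- 0.01
    arr[, , 4L] <- matrix(0.97 * soil[, 1L], h, w)
    arr[, , 5L] <- matrix(0.97 * soil[, 2L], h, w)
    for (i in seq_len(nrow(config@plots))) {
      roi <- config@plots[i, ]
      g <- match(roi$n_rate, rates) - 1L
      mu <- .groupMeanAbundance(g, length(rates))
      # plot-level jitter around the group mean (field heterogeneity)
      muPlot <- drop(rdirichlet(1L, config@plotConcentration * mu))
      rows <- roiRows(roi); cols <- roiCols(roi)
      np <- length(rows) * length(cols)
      a <- rdirichlet(np, config@pixelConcentration * muPlot)
      block <- array(a, dim = c(length(rows), length(cols), nem))
      for (k in seq_len(nem))
        block[, , k] <- .smooth2d(block[, , k], kern)
      # re-project to the simplex (smoothing preserves sums up to fp error)
      s <- apply(block, c(1, 2), sum)
      for (k in seq_len(nem)) block[, , k] <- block[, , k] / s
      arr[rows, cols, ] <- block
    }
    arr
  })
}

#' Render a synthetic scene to digital numbers
#'
#' Applies the linear mixing model per pixel (reflectance = library x
#' abundance), adds Gaussian reflectance noise, clips to [0, 1.2] (the 100%
#' panel plus noise may legitimately exceed 1), and converts to DN by
#' inverting the empirical line: DN = (reflectance - B) / G per band. The
#' four calibration panels are rendered at their nominal reflectances
#' through the same noise and DN transform.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @param library an \linkS4class{EndmemberLibrary} on the config bands.
#' @param abundances rows x cols x 5 abundance array from
#'   \code{\link{generateAbundanceField}}.
#' @param seed RNG seed for the reflectance noise (default config seed + 1).
#' @return list with \code{image} (DN \linkS4class{SpectralImage}),
#'   \code{panels} (data.frame panel_id, reflectance, band_nm, mean_DN) and
#'   \code{truth} (a \linkS4class{GroundTruth}, yields not yet filled).
#' @export
renderScene <- function(config, library = defaultEndmemberLibrary(),
                        abundances, seed = config@seed + 1L) {
  validObject(config)
  if (!isTRUE(all.equal(bandCenters(library), config@bandCenters)))
    stopf("library bands do not match config bands")
  if (any(config@gains == 0)) stopf("invalid config: zero gain")
  h <- config@height; w <- config@width
  M <- spectra(library)                       # 6 x 5
  A <- pixelMatrix(abundances)                # npix x 5
  refl <- A %*% t(M)                          # npix x 6
  withSeed(seed, {
    if (config@noiseSigma > 0)
      refl <- refl + matrix(stats::rnorm(length(refl), 0, config@noiseSigma),
                            nrow = nrow(refl))
    reflArr <- pixelArray(pmin(pmax(refl, 0), 1.2), h, w)
    # panels: flat spectrum at nominal reflectance, same noise model
    for (i in seq_len(nrow(config@panels))) {
      p <- config@panels[i, ]
      rows <- roiRows(p); cols <- roiCols(p)
      for (b in 1:6) {
        v <- p$reflectance
        if (config@noiseSigma > 0)
          v <- v + stats::rnorm(length(rows) * length(cols), 0,
                                config@noiseSigma)
        reflArr[rows, cols, b] <- pmin(pmax(v, 0), 1.2)
      }
    }
    dn <- reflArr
    for (b in 1:6)
      dn[, , b] <- (reflArr[, , b] - config@biases[b]) / config@gains[b]
    if (config@quantize) dn <- pmin(pmax(round(dn), 0), 1023)
    image <- SpectralImage(dn, config@bandCenters, "DN")
    panelDN <- do.call(rbind, lapply(seq_len(nrow(config@panels)), function(i) {
      p <- config@panels[i, ]
      rows <- roiRows(p); cols <- roiCols(p)
      data.frame(panel_id = p$panel_id, reflectance = p$reflectance,
                 band_nm = config@bandCenters,
                 mean_DN = vapply(1:6, function(b) mean(dn[rows, cols, b]),
                                  numeric(1)))
    }))
    nPlots <- nrow(config@plots)
    plotAb <- matrix(NA_real_, nPlots, 5,
                     dimnames = list(config@plots$plot_id,
                                     endmemberNames(library)))
    for (i in seq_len(nPlots)) {
      roi <- config@plots[i, ]
      plotAb[i, ] <- apply(abundances[roiRows(roi), roiCols(roi), ,
                                      drop = FALSE], 3, mean)
    }
    plotRefl <- plotAb %*% t(M)
    colnames(plotRefl) <- as.character(config@bandCenters)
    truth <- new("GroundTruth", abundances = abundances,
                 plotAbundances = plotAb, plotReflectance = plotRefl,
                 yields = numeric(0), gains = config@gains,
                 biases = config@biases, library = library)
    list(image = image, panels = panelDN, truth = truth)
  })
}

# Abundance combination used in yield predictors; m is plots x 5 with the
# standard endmember column order.
.abundanceCombo <- function(m, combo) {
  switch(combo,
         "none" = rep(1, nrow(m)),
         "FL" = m[, "FL"],
         "SE-LF+SS-LF" = m[, "SE-LF"] + m[, "SS-LF"],
         "SS-LF" = m[, "SS-LF"],
         stopf("unknown predictor abundance combination '%s'", combo))
}

#' Generate per-plot yields from the configured linear model
#'
#' yield_p = a * predictor_p + b + eps_p, eps_p ~ N(0, sigma_y^2), where the
#' predictor is the configured vegetation index of the plot's noiseless true
#' mean reflectance times the configured abundance combination of the true
#' plot-mean abundances. Defaults are calibrated so noiseless yields span
#' roughly 1000--3500 kg/ha across the eight nitrogen groups.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @param truth the \linkS4class{GroundTruth} from \code{\link{renderScene}}.
#' @param library the \linkS4class{EndmemberLibrary} used for mixing.
#' @param seed RNG seed for yield noise (default config seed + 2).
#' @return named numeric vector of yields (kg/ha), one per plot.
#' @export
generateYields <- function(config, truth, library = truth@library,
                           seed = config@seed + 2L) {
  vi <- viImageMatrix(truth@plotReflectance, config@yieldVI)
  pred <- vi * .abundanceCombo(truth@plotAbundances, config@yieldAbundance)
  withSeed(seed, {
    y <- config@yieldSlope * pred + config@yieldIntercept +
      stats::rnorm(length(pred), 0, config@yieldSigma)
    stats::setNames(y, config@plots$plot_id)
  })
}

#' Synthesize a complete ground-truthed scene
#'
#' Convenience wrapper running \code{\link{generateAbundanceField}},
#' \code{\link{renderScene}} and \code{\link{generateYields}} in sequence.
#' Identical config and seed give bit-identical output.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @param library endmember library (default \code{defaultEndmemberLibrary()}).
#' @return list: \code{image} (DN), \code{panels}, \code{truth} (with yields),
#'   \code{rois} (the plot data.frame), \code{yields}, \code{library},
#'   \code{config}.
#' @export
synthesizeScene <- function(config = sceneConfig(),
                            library = defaultEndmemberLibrary()) {
  ab <- generateAbundanceField(config)
  sc <- renderScene(config, library, ab)
  y <- generateYields(config, sc$truth, library)
  sc$truth@yields <- y
  list(image = sc$image, panels = sc$panels, truth = sc$truth,
       rois = config@plots, yields = y, library = library, config = config)
}
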