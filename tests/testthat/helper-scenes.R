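# Shared fixtures, all generated in code.

# Desk-scale scene for fast module tests: 200 x 140 px, 24 plots of 40 x 18.
smallConfig <- function(seed = 1L, ...) {
  sceneConfig(width = 200L, height = 140L, plotWidth = 40L, plotHeight = 18L,
              seed = seed, ...)
}

# rows x cols x channels array -> pixel matrix (column-major pixel order).
pixmat <- function(a) matrix(a, nrow = dim(a)[1] * dim(a)[2], ncol = dim(a)[3])

# Logical mask of panel pixels for a config.
panelMask <- function(config) {
  m <- matrix(FALSE, config@height, config@width)
  for (i in seq_len(nrow(config@panels))) {
    p <- config@panels[i, ]
    m[(p$y0 + 1):p$y1, (p$x0 + 1):p$x1] <- TRUE
  }
  m
}

# Independent normal-equations OLS oracle (explicit 2x2 solve, no lm()).
olsOracle <- function(x, y) {
  X <- cbind(1, x)
  ab <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% ab
  list(intercept = ab[1], slope = ab[2],
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
       ssres = sum(res^2))
}

# Synthetic 1-nm fine spectra covering 350-1100 nm for resampling tests.
fineSpectraFixture <- function() {
  wl <- 350:1100
  rbind(
    data.frame(endmember = "flat", wavelength_nm = wl, reflectance = 0.3),
    data.frame(endmember = "ramp", wavelength_nm = wl,
               reflectance = wl / 1000))
}
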