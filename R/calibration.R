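#' Fit the empirical line from calibration panel readings
#'
#' For every band, solves the ordinary-least-squares problem
#' reflectance = B + G * DN over the calibration panels via the normal
#' equations (the design matrix is [1, DN]). With exactly two panels the fit
#' is exact interpolation. The standard panel set has nominal reflectances
#' 0.06, 0.24, 0.48 and 1.00.
#'
#' @param panels data.frame with columns \code{reflectance}, \code{band_nm}
#'   and \code{mean_DN} (one row per panel x band), as written by the
#'   synthetic generator or extracted from panel ROIs.
#' @return An \linkS4class{EmpiricalLineModel}.
#' @examples
#' p <- expand.grid(reflectance = c(0.06, 1.00), band_nm = rapemixBands)
#' p$mean_DN <- (p$reflectance - 0.01) / 5e-4
#' fitEmpiricalLine(p)
#' @export
fitEmpiricalLine <- function(panels) {
  need <- c("reflectance", "band_nm", "mean_DN")
  if (!all(need %in% names(panels)))
    stopf("panels must have columns %s", paste(need, collapse = ", "))
  bands <- sort(unique(panels$band_nm))
  n <- length(bands)
  G <- B <- RSS <- numeric(n)
  for (i in seq_len(n)) {
    sub <- panels[panels$band_nm == bands[i], ]
    if (nrow(sub) < 2L)
      stopf("insufficient panels for band %g nm: need >= 2, got %d",
            bands[i], nrow(sub))
    dn <- sub$mean_DN
    if (length(unique(dn)) < 2L)
      stopf("rank-deficient panel DNs in band %g nm: all values identical",
            bands[i])
    X <- cbind(1, dn)
    coefs <- solve(crossprod(X), crossprod(X, sub$reflectance))
    B[i] <- coefs[1L]
    G[i] <- coefs[2L]
    RSS[i] <- sum((sub$reflectance - X %*% coefs)^2)
  }
  new("EmpiricalLineModel", gains = G, biases = B, rss = RSS,
      bandCenters = as.numeric(bands))
}

#' Convert a DN image to surface reflectance
#'
#' Applies the empirical line per band: reflectance = DN * G + B. Values are
#' deliberately not clipped; out-of-range pixels (reflectance below 0 or
#' above 1) are counted in the \code{"outOfRange"} attribute so unmixing
#' residuals stay undistorted.
#'
#' @param image a DN \linkS4class{SpectralImage}.
#' @param model an \linkS4class{EmpiricalLineModel} on the same bands.
#' @return a reflectance \linkS4class{SpectralImage} with attribute
#'   \code{outOfRange} (integer pixel-band count outside [0, 1]).
#' @export
applyCalibration <- function(image, model) {
  stopifnot(is(image, "SpectralImage"), is(model, "EmpiricalLineModel"))
  if (imageUnit(image) != "DN")
    stopf("image is already in '%s' units; applyCalibration expects DN",
          imageUnit(image))
  if (!isTRUE(all.equal(bandCenters(image), bandCenters(model))))
    stopf("image bands do not match calibration model bands")
  v <- imageData(image)
  for (b in seq_along(model@gains))
    v[, , b] <- v[, , b] * model@gains[b] + model@biases[b]
  out <- SpectralImage(v, bandCenters(image), "reflectance")
  attr(out, "outOfRange") <- sum(v < 0 | v > 1)
  out
}

#' Extract mean panel DN readings from a DN image
#'
#' Convenience helper turning panel rectangles into the panel observation
#' table \code{\link{fitEmpiricalLine}} consumes; the extraction statistic is
#' the plain arithmetic mean over the rectangle.
#'
#' @param image a DN \linkS4class{SpectralImage}.
#' @param panelROIs data.frame: panel_id, reflectance, x0, y0, x1, y1
#'   (0-based, half-open, x = column).
#' @return data.frame panel_id, reflectance, band_nm, mean_DN.
#' @export
extractPanelDN <- function(image, panelROIs) {
  stopifnot(is(image, "SpectralImage"))
  v <- imageData(image)
  do.call(rbind, lapply(seq_len(nrow(panelROIs)), function(i) {
    p <- panelROIs[i, ]
    rows <- roiRows(p); cols <- roiCols(p)
    data.frame(panel_id = p$panel_id, reflectance = p$reflectance,
               band_nm = bandCenters(image),
               mean_DN = vapply(seq_along(bandCenters(image)),
                                function(b) mean(v[rows, cols, b]),
                                numeric(1)))
  }))
}
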