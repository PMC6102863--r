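#' Fully constrained unmixing of a single reflectance vector
#'
#' Returns the minimiser of \eqn{\|r - M a\|^2} subject to \eqn{a \ge 0} and
#' \eqn{\sum a = 1}: the pixel's fractional endmember abundances under the
#' linear mixing model with the physical constraints enforced exactly. Solved
#' by Lawson--Hanson NNLS on a sum-to-one-augmented system with an exact
#' equality-constrained refinement (see the package vignette for numerical
#' details).
#'
#' @param r numeric length-6 reflectance vector (standard band order).
#' @param lib an \linkS4class{EndmemberLibrary}.
#' @return list: \code{abundance} (named five-vector) and \code{residual}
#'   (RMS reconstruction residual over bands).
#' @examples
#' lib <- defaultEndmemberLibrary()
#' unmixPixel(spectra(lib)[, "FL"], lib)   # pure flower
#' @export
unmixPixel <- function(r, lib) {
  stopifnot(is(lib, "EndmemberLibrary"))
  if (any(!is.finite(r)))
    stopf("invalid pixel: non-finite reflectance")
  M <- spectra(lib)
  if (length(r) != nrow(M))
    stopf("reflectance length %d does not match library bands %d",
          length(r), nrow(M))
  if (qr(M)$rank < ncol(M)) stopf("degenerate library: rank deficient")
  out <- .fclsCpp(matrix(r, nrow = 1L), M)
  list(abundance = stats::setNames(out[1L, seq_len(ncol(M))],
                                   endmemberNames(lib)),
       residual = out[1L, ncol(M) + 1L])
}

#' Unmix every pixel of a reflectance image
#'
#' Applies the fully constrained solver pixel by pixel (each pixel is
#' independent; results do not depend on visiting order) and returns the
#' abundance map plus the per-pixel RMS reconstruction residual.
#'
#' @param image a reflectance \linkS4class{SpectralImage}.
#' @param lib an \linkS4class{EndmemberLibrary} on the same bands.
#' @return An \linkS4class{AbundanceMap}.
#' @export
unmixImage <- function(image, lib) {
  stopifnot(is(image, "SpectralImage"), is(lib, "EndmemberLibrary"))
  if (imageUnit(image) != "reflectance")
    stopf("unmixImage requires a reflectance image (got '%s')",
          imageUnit(image))
  if (!isTRUE(all.equal(bandCenters(image), bandCenters(lib))))
    stopf("image bands do not match library bands")
  M <- spectra(lib)
  if (qr(M)$rank < ncol(M)) stopf("degenerate library: rank deficient")
  R <- pixelMatrix(imageData(image))
  bad <- which(!is.finite(rowSums(R)))
  if (length(bad))
    stopf("invalid pixel at (row %d, col %d): non-finite reflectance",
          (bad[1L] - 1L) %% dim(image)[1L] + 1L,
          (bad[1L] - 1L) %/% dim(image)[1L] + 1L)
  out <- .fclsCpp(R, M)
  d <- dim(image)
  nem <- ncol(M)
  new("AbundanceMap",
      values = pixelArray(out[, seq_len(nem), drop = FALSE], d[1], d[2]),
      endmembers = endmemberNames(lib),
      residual = matrix(out[, nem + 1L], d[1], d[2]))
}

#' Brute-force simplex grid search (reference oracle)
#'
#' Exhaustively enumerates every abundance vector on a regular grid over the
#' simplex (step 1/steps) and reports, per pixel, the smallest squared
#' reconstruction error and its abundance vector. Exponentially slower than
#' the constrained solver and entirely independent of it; intended as a
#' correctness oracle in tests, not for production use.
#'
#' @param R numeric matrix, pixels x bands reflectance.
#' @param lib an \linkS4class{EndmemberLibrary}.
#' @param steps grid resolution (default 100, i.e. 0.01 steps).
#' @return list: \code{objective} (per-pixel minimum of \eqn{\|r - Ma\|^2})
#'   and \code{abundance} (pixels x endmembers matrix of the argmin).
#' @export
simplexGridSearch <- function(R, lib, steps = 100L) {
  stopifnot(is(lib, "EndmemberLibrary"))
  if (is.vector(R)) R <- matrix(R, nrow = 1L)
  .gridSearchCpp(R, spectra(lib), as.integer(steps))
}

#' Squared reconstruction error of an abundance assignment
#'
#' @param r reflectance vector (or pixels x bands matrix).
#' @param lib an \linkS4class{EndmemberLibrary}.
#' @param a abundance vector (or pixels x endmembers matrix).
#' @return numeric vector of \eqn{\|r - Ma\|^2} per pixel.
#' @export
unmixObjective <- function(r, lib, a) {
  M <- spectra(lib)
  if (is.vector(r)) r <- matrix(r, nrow = 1L)
  if (is.vector(a)) a <- matrix(a, nrow = 1L)
  rowSums((r - a %*% t(M))^2)
}
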