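#' Vegetation index names understood by the pipeline
#'
#' Ten indices computable from the six-band reflectance vector. Matching is
#' case-insensitive.
#' @export
viNames <- c("NDVI", "CIrededge", "CIgreen", "VARI", "RVI",
             "DVI", "RDVI", "EVI", "TVI", "SAVI")

.matchVI <- function(name) {
  i <- match(tolower(name), tolower(viNames))
  if (is.na(i)) stopf("unknown index '%s' (known: %s)", name,
                      paste(viNames, collapse = ", "))
  viNames[i]
}

# Core vectorised evaluation; R is an n x 6 matrix ordered by wavelength
# (490, 550, 670, 720, 800, 900 nm). Returns values plus a flag per row
# ("" / "division-by-zero" / "out-of-domain"). Reflectance must be on the
# 0-1 scale: the additive constants in EVI and SAVI are only meaningful there.
.viCore <- function(name, R, L = 0.5) {
  name <- .matchVI(name)
  b490 <- R[, 1L]; b550 <- R[, 2L]; b670 <- R[, 3L]
  b720 <- R[, 4L]; b800 <- R[, 5L]
  flags <- character(nrow(R))
  guard <- function(den) {
    bad <- abs(den) < 1e-12
    flags[bad & flags == ""] <<- "division-by-zero"
    ifelse(bad, NA_real_, den)
  }
  v <- switch(name,
    NDVI = (b800 - b670) / guard(b800 + b670),
    CIrededge = b800 / guard(b720) - 1,
    CIgreen = b800 / guard(b550) - 1,
    VARI = (b550 - b670) / guard(b550 + b670),
    RVI = b800 / guard(b670),
    DVI = b800 - b670,
    RDVI = {
      ndvi <- (b800 - b670) / guard(b800 + b670)
      rad <- ndvi * (b800 - b670) / 2
      neg <- !is.na(rad) & rad < 0
      flags[neg & flags == ""] <- "out-of-domain"
      ifelse(neg, NA_real_, sqrt(pmax(rad, 0)))
    },
    EVI = 2.5 * (b800 - b670) / guard(b800 + 6 * b670 - 7.5 * b490 + 1),
    TVI = 0.5 * (120 * (b800 - b550) - 200 * (b670 - b550)),
    SAVI = (1 + L) * (b800 - b670) / guard(b800 + b670 + L))
  list(name = name, values = as.numeric(v), flags = flags)
}

# Vector of VI values for a plots x 6 reflectance matrix (internal).
viImageMatrix <- function(R, name, L = 0.5) .viCore(name, R, L)$values

#' Compute one vegetation index from a six-band reflectance vector
#'
#' Evaluates the named index literally from its defining formula on
#' reflectance at 490/550/670/720/800/900 nm (0-1 scale). Denominators of
#' magnitude below 1e-12 and a negative RDVI radicand yield a flagged NA
#' rather than an error.
#'
#' @param name index name (see \code{\link{viNames}}; case-insensitive).
#' @param r numeric length-6 reflectance vector ordered by wavelength.
#' @param L SAVI soil adjustment factor (default 0.5, Huete's canonical
#'   value); ignored by the other indices.
#' @return list of class \code{VIResult}: \code{name}, \code{value},
#'   \code{flag} ("" when clean).
#' @examples
#' computeVI("NDVI", c(0.05, 0.10, 0.08, 0.20, 0.50, 0.55))
#' @export
computeVI <- function(name, r, L = 0.5) {
  if (length(r) != 6L || any(!is.finite(r)))
    stopf("reflectance vector must be six finite values")
  out <- .viCore(name, matrix(r, nrow = 1L), L)
  structure(list(name = out$name, value = out$values[1L],
                 flag = out$flags[1L]),
            class = "VIResult")
}

#' @export
print.VIResult <- function(x, ...) {
  cat(sprintf("%s = %.6g%s\n", x$name, x$value,
              if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Compute a vegetation index image
#'
#' Elementwise application of \code{\link{computeVI}} to every pixel of a
#' reflectance image. Flag counts are attached as the \code{"flagCounts"}
#' attribute of the returned grid.
#'
#' @param image a reflectance \linkS4class{SpectralImage}.
#' @param name index name.
#' @param L SAVI soil factor.
#' @return numeric matrix (rows x cols) of index values with attribute
#'   \code{flagCounts} (named integer vector).
#' @export
viImage <- function(image, name, L = 0.5) {
  stopifnot(is(image, "SpectralImage"))
  if (imageUnit(image) != "reflectance")
    stopf("viImage requires a reflectance image (got unit '%s')",
          imageUnit(image))
  d <- dim(image)
  out <- .viCore(name, pixelMatrix(imageData(image)), L)
  m <- matrix(out$values, d[1], d[2])
  fl <- out$flags[nzchar(out$flags)]
  attr(m, "flagCounts") <- c(table(fl))
  m
}
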