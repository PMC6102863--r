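#' Built-in five-endmember reflectance library
#'
#' Reference reflectance of the five scene components at the six camera bands:
#' flower (FL), sessile leaf (SE-LF), short-stalk leaf (SS-LF), wet soil
#' (W-soil) and dry soil (D-soil). The values encode the qualitative spectral
#' relations observed in flowering rapeseed canopies: flower blue reflectance
#' (0.03) below half the leaf value (0.08) but higher than leaf in the green,
#' red and NIR; the sessile leaf greener-dark and slightly NIR-brighter than
#' the short-stalk leaf; wet soil below dry soil at every wavelength. The
#' matrix has full column rank so constrained unmixing is well posed.
#'
#' @param bandCenters band centres in nm; must be the standard six
#'   (490/550/670/720/800/900), otherwise an unsupported-bands error is raised.
#' @return An \linkS4class{EndmemberLibrary}.
#' @examples
#' lib <- defaultEndmemberLibrary()
#' spectra(lib)["490", "FL"]   # 0.03
#' @export
defaultEndmemberLibrary <- function(bandCenters = rapemixBands) {
  .checkBands(bandCenters)
  m <- cbind(
    `FL`     = c(0.030, 0.300, 0.420, 0.550, 0.650, 0.660),
    `SE-LF`  = c(0.080, 0.090, 0.050, 0.280, 0.520, 0.530),
    `SS-LF`  = c(0.080, 0.120, 0.055, 0.300, 0.500, 0.510),
    `W-soil` = c(0.080, 0.100, 0.140, 0.160, 0.180, 0.200),
    `D-soil` = c(0.180, 0.220, 0.280, 0.300, 0.330, 0.350))
  EndmemberLibrary(m, bandCenters)
}

#' Resample fine (1-nm) endmember spectra to the camera bands
#'
#' Field spectroradiometer spectra (e.g. 350--1100 nm at ~1 nm resolution) are
#' converted to the six-band library by averaging each spectrum over the
#' closed band-pass window [centre - width/2, centre + width/2].
#'
#' @param fineSpectra data.frame with columns \code{endmember},
#'   \code{wavelength_nm}, \code{reflectance}; wavelengths at 1-nm steps.
#' @param bandCenters band centres in nm.
#' @param bandWidth full band-pass width in nm (default 10).
#' @return An \linkS4class{EndmemberLibrary}.
#' @export
resampleLibrary <- function(fineSpectra, bandCenters = rapemixBands,
                            bandWidth = 10) {
  need <- c("endmember", "wavelength_nm", "reflectance")
  if (!all(need %in% names(fineSpectra)))
    stopf("fineSpectra must have columns %s", paste(need, collapse = ", "))
  ems <- unique(fineSpectra$endmember)
  half <- bandWidth / 2
  m <- matrix(NA_real_, nrow = length(bandCenters), ncol = length(ems),
              dimnames = list(as.character(bandCenters), ems))
  for (e in ems) {
    sp <- fineSpectra[fineSpectra$endmember == e, ]
    for (i in seq_along(bandCenters)) {
      ctr <- bandCenters[i]
      lo <- ctr - half; hi <- ctr + half
      inwin <- sp$wavelength_nm >= lo & sp$wavelength_nm <= hi
      # coverage check: need samples spanning the whole window
      if (!any(inwin) || min(sp$wavelength_nm[inwin]) > lo ||
          max(sp$wavelength_nm[inwin]) < hi)
        stopf("missing wavelengths for band %g nm (endmember %s): need full coverage of [%g, %g]",
              ctr, e, lo, hi)
      m[i, e] <- mean(sp$reflectance[inwin])
    }
  }
  EndmemberLibrary(m, bandCenters)
}
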