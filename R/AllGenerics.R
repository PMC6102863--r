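#' Band centres of an object
#'
#' @param x a SpectralImage, EndmemberLibrary or EmpiricalLineModel.
#' @return numeric vector of band centres in nm.
#' @export
setGeneric("bandCenters", function(x) standardGeneric("bandCenters"))

#' @rdname bandCenters
setMethod("bandCenters", "SpectralImage", function(x) x@bandCenters)
#' @rdname bandCenters
setMethod("bandCenters", "EndmemberLibrary", function(x) x@bandCenters)
#' @rdname bandCenters
setMethod("bandCenters", "EmpiricalLineModel", function(x) x@bandCenters)

#' Pixel values of an image-like object
#'
#' @param x a SpectralImage or AbundanceMap.
#' @return the underlying numeric array (rows x cols x channels).
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @rdname imageData
setMethod("imageData", "SpectralImage", function(x) x@values)
#' @rdname imageData
setMethod("imageData", "AbundanceMap", function(x) x@values)

#' Unit tag of a SpectralImage ("DN" or "reflectance")
#'
#' @param x a SpectralImage.
#' @return character scalar.
#' @export
setGeneric("imageUnit", function(x) standardGeneric("imageUnit"))

#' @rdname imageUnit
setMethod("imageUnit", "SpectralImage", function(x) x@imageUnit)

#' Endmember names
#'
#' @param x an EndmemberLibrary or AbundanceMap.
#' @return character vector of endmember names.
#' @export
setGeneric("endmemberNames", function(x) standardGeneric("endmemberNames"))

#' @rdname endmemberNames
setMethod("endmemberNames", "EndmemberLibrary", function(x) colnames(x@spectra))
#' @rdname endmemberNames
setMethod("endmemberNames", "AbundanceMap", function(x) x@endmembers)

#' Endmember reflectance matrix (bands x endmembers)
#'
#' @param x an EndmemberLibrary.
#' @return numeric matrix.
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @rdname spectra
setMethod("spectra", "EndmemberLibrary", function(x) x@spectra)

#' Calibration gains and biases
#'
#' @param x an EmpiricalLineModel.
#' @return named numeric vector, one entry per band.
#' @export
setGeneric("gains", function(x) standardGeneric("gains"))
#' @rdname gains
setMethod("gains", "EmpiricalLineModel",
          function(x) stats::setNames(x@gains, x@bandCenters))

#' @rdname gains
#' @export
setGeneric("biases", function(x) standardGeneric("biases"))
#' @rdname gains
setMethod("biases", "EmpiricalLineModel",
          function(x) stats::setNames(x@biases, x@bandCenters))

#' Per-pixel RMS reconstruction residual of an unmixing result
#'
#' @param x an AbundanceMap.
#' @return numeric matrix, rows x cols.
#' @export
setGeneric("residualMap", function(x) standardGeneric("residualMap"))

#' @rdname residualMap
setMethod("residualMap", "AbundanceMap", function(x) x@residual)

setMethod("dim", "SpectralImage", function(x) dim(x@values))
setMethod("dim", "AbundanceMap", function(x) dim(x@values))

setMethod("show", "SpectralImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("SpectralImage: %d x %d pixels, %d bands [%s nm], unit = %s\n",
              d[1], d[2], d[3],
              paste(object@bandCenters, collapse = "/"), object@imageUnit))
})

setMethod("show", "EndmemberLibrary", function(object) {
  cat(sprintf("EndmemberLibrary: %d endmembers x %d bands\n",
              ncol(object@spectra), nrow(object@spectra)))
  print(round(t(object@spectra), 4))
})

setMethod("show", "AbundanceMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("AbundanceMap: %d x %d pixels, endmembers: %s\n",
              d[1], d[2], paste(object@endmembers, collapse = ", ")))
  cat(sprintf("  mean RMS residual: %.3g\n", mean(object@residual)))
})

setMethod("show", "EmpiricalLineModel", function(object) {
  cat("EmpiricalLineModel (reflectance = DN * G + B):\n")
  print(data.frame(band_nm = object@bandCenters, gain = object@gains,
                   bias = object@biases, rss = object@rss))
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(
    "SceneConfig: %d x %d px, %d plots, sigma = %g, yield ~ %g * (%s x %s) + %g, seed = %d\n",
    object@width, object@height, nrow(object@plots), object@noiseSigma,
    object@yieldSlope, object@yieldVI, object@yieldAbundance,
    object@yieldIntercept, object@seed))
})

setMethod("show", "CrossValReport", function(object) {
  cat(sprintf("CrossValReport (K = %d folds):\n", object@summary$k))
  print(object@summary, row.names = FALSE)
})
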