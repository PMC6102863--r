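#' @useDynLib rapemix, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Standard band centres of the six-band camera (nm)
#'
#' The pipeline is built around a six-lens multispectral camera whose band-pass
#' filters are centred at 490, 550, 670, 720, 800 and 900 nm (10 nm width).
#' All containers carry these centres and validity methods enforce them where
#' an operation is only defined for the standard set.
#'
#' @export
rapemixBands <- c(490, 550, 670, 720, 800, 900)

.checkBands <- function(bands) {
  if (length(bands) != 6L || !isTRUE(all.equal(as.numeric(bands), rapemixBands)))
    stop("unsupported bands: expected the six standard centres ",
         paste(rapemixBands, collapse = "/"), " nm", call. = FALSE)
  invisible(as.numeric(bands))
}

#' SpectralImage: a multi-band pixel grid
#'
#' Container for the six-band raster the pipeline flows through. Pixel values
#' are held in a \code{rows x cols x bands} array, tagged with band centres and
#' a unit ("DN" for raw digital numbers, "reflectance" after calibration).
#'
#' @slot values numeric array, \code{rows x cols x bands}.
#' @slot bandCenters numeric, band centres in nm, ascending.
#' @slot imageUnit character, "DN" or "reflectance".
#' @aliases SpectralImage
#' @exportClass SpectralImage
setClass("SpectralImage",
  representation(values = "array", bandCenters = "numeric",
                 imageUnit = "character"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L)
      return("values must be a rows x cols x bands array")
    if (d[3] != length(object@bandCenters))
      return("third array dimension must match the number of band centres")
    if (is.unsorted(object@bandCenters, strictly = TRUE))
      return("band centres must be strictly ascending")
    if (!object@imageUnit %in% c("DN", "reflectance"))
      return("imageUnit must be 'DN' or 'reflectance'")
    TRUE
  })

#' Construct a SpectralImage
#'
#' @param values numeric array, \code{rows x cols x bands}.
#' @param bandCenters band centres in nm.
#' @param unit "DN" or "reflectance".
#' @return A \linkS4class{SpectralImage}.
#' @export
SpectralImage <- function(values, bandCenters = rapemixBands,
                          unit = c("DN", "reflectance")) {
  unit <- match.arg(unit)
  new("SpectralImage", values = values, bandCenters = as.numeric(bandCenters),
      imageUnit = unit)
}

#' EndmemberLibrary: reflectance spectra of the scene's pure components
#'
#' The mixing matrix of the linear model: one column per endmember (flower,
#' sessile leaf, short-stalk leaf, wet soil, dry soil), one row per band.
#' Validity requires full column rank so the constrained inversion is well
#' posed, and reflectance within [0, 1.2].
#'
#' @slot spectra numeric matrix, bands x endmembers, dimnames set.
#' @slot bandCenters numeric, band centres in nm.
#' @aliases EndmemberLibrary
#' @exportClass EndmemberLibrary
setClass("EndmemberLibrary",
  representation(spectra = "matrix", bandCenters = "numeric"),
  validity = function(object) {
    m <- object@spectra
    if (nrow(m) != length(object@bandCenters))
      return("spectra rows must match band centres")
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
      return("endmember columns must carry unique names")
    if (any(!is.finite(m)) || any(m < 0) || any(m > 1.2))
      return("endmember reflectance must be finite and within [0, 1.2]")
    if (qr(m)$rank < ncol(m))
      return("endmember matrix is rank deficient (collinear spectra)")
    TRUE
  })

#' Construct an EndmemberLibrary
#'
#' @param spectra bands x endmembers reflectance matrix with column names.
#' @param bandCenters band centres in nm.
#' @return An \linkS4class{EndmemberLibrary}.
#' @export
EndmemberLibrary <- function(spectra, bandCenters = rapemixBands) {
  rownames(spectra) <- as.character(bandCenters)
  new("EndmemberLibrary", spectra = spectra,
      bandCenters = as.numeric(bandCenters))
}

#' AbundanceMap: per-pixel endmember fractions
#'
#' Result of fully constrained unmixing: for every pixel a vector of
#' endmember fractions in [0, 1] summing to 1, plus the per-pixel RMS
#' reconstruction residual over bands.
#'
#' @slot values numeric array, \code{rows x cols x endmembers}.
#' @slot endmembers character, endmember names in column order.
#' @slot residual numeric matrix, \code{rows x cols} RMS residual.
#' @aliases AbundanceMap
#' @exportClass AbundanceMap
setClass("AbundanceMap",
  representation(values = "array", endmembers = "character",
                 residual = "matrix"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L || d[3] != length(object@endmembers))
      return("values must be rows x cols x endmembers")
    if (!all(dim(object@residual) == d[1:2]))
      return("residual must match the pixel grid")
    TRUE
  })

#' EmpiricalLineModel: per-band DN-to-reflectance line
#'
#' Gains and biases of the empirical-line calibration
#' \eqn{\rho(\lambda) = DN(\lambda) G_\lambda + B_\lambda}, fitted per band by
#' ordinary least squares over the calibration panels, with the per-band
#' residual sum of squares as a fit diagnostic.
#'
#' @slot gains numeric, reflectance per DN, one per band.
#' @slot biases numeric, reflectance, one per band.
#' @slot rss numeric, per-band residual sum of squares over the panels.
#' @slot bandCenters numeric, band centres in nm.
#' @aliases EmpiricalLineModel
#' @exportClass EmpiricalLineModel
setClass("EmpiricalLineModel",
  representation(gains = "numeric", biases = "numeric", rss = "numeric",
                 bandCenters = "numeric"),
  validity = function(object) {
    n <- length(object@bandCenters)
    if (length(object@gains) != n || length(object@biases) != n ||
        length(object@rss) != n)
      return("gains, biases and rss must have one entry per band")
    if (any(!is.finite(object@gains)) || any(object@gains == 0))
      return("gains must be finite and nonzero")
    if (any(!is.finite(object@biases)))
      return("biases must be finite")
    TRUE
  })

#' SceneConfig: the stated world of the synthetic generator
#'
#' Holds every parameter of the synthetic rapeseed scene: image size, plot
#' layout with nitrogen rates, true sensor gain/bias per band used to render
#' digital numbers, reflectance noise, Dirichlet concentrations controlling
#' within-plot abundance spread, the yield model (predictor, slope, intercept,
#' noise), panel geometry and the master seed. See \code{\link{sceneConfig}}
#' for defaults.
#'
#' @slot width,height integer image size in pixels (columns, rows).
#' @slot bandCenters numeric, the six standard band centres (nm).
#' @slot gains,biases numeric per-band true sensor gain/bias (ground truth
#'   for calibration recovery).
#' @slot noiseSigma numeric, additive reflectance noise sd (unitless).
#' @slot plots data.frame: plot_id, n_rate, x0, y0, x1, y1 (0-based,
#'   half-open pixel coordinates, x = column, y = row).
#' @slot panels data.frame: panel_id, reflectance, x0, y0, x1, y1.
#' @slot pixelConcentration,plotConcentration numeric Dirichlet concentration
#'   totals for pixel draws and plot-level mean jitter.
#' @slot yieldVI,yieldAbundance character, predictor of the yield model.
#' @slot yieldSlope,yieldIntercept,yieldSigma numeric yield model parameters
#'   (kg/ha; sigma is the plot-level noise sd).
#' @slot quantize logical, round DN to 10-bit integers when TRUE.
#' @slot seed integer master seed.
#' @aliases SceneConfig
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(width = "integer", height = "integer",
                 bandCenters = "numeric",
                 gains = "numeric", biases = "numeric",
                 noiseSigma = "numeric",
                 plots = "data.frame", panels = "data.frame",
                 pixelConcentration = "numeric",
                 plotConcentration = "numeric",
                 yieldVI = "character", yieldAbundance = "character",
                 yieldSlope = "numeric", yieldIntercept = "numeric",
                 yieldSigma = "numeric",
                 quantize = "logical", seed = "integer"),
  validity = function(object) {
    ok <- try(.checkBands(object@bandCenters), silent = TRUE)
    if (inherits(ok, "try-error"))
      return("band centres must be the six standard values")
    if (length(object@gains) != 6L || any(object@gains == 0) ||
        any(!is.finite(object@gains)))
      return("invalid config: six finite nonzero gains required")
    if (length(object@biases) != 6L || any(!is.finite(object@biases)))
      return("six finite biases required")
    if (object@noiseSigma < 0 || object@yieldSigma < 0)
      return("noise sigmas must be >= 0")
    p <- object@plots
    need <- c("plot_id", "n_rate", "x0", "y0", "x1", "y1")
    if (!all(need %in% names(p)))
      return("plots must have plot_id, n_rate, x0, y0, x1, y1")
    if (anyDuplicated(p$plot_id)) return("plot ids must be unique")
    if (any(p$x0 < 0 | p$y0 < 0 | p$x1 > object@width | p$y1 > object@height))
      return("plot rectangles must lie within image bounds")
    if (any(p$x1 <= p$x0 | p$y1 <= p$y0))
      return("plot rectangles must be non-empty")
    if (nrow(p) > 1L) {
      for (i in seq_len(nrow(p) - 1L)) {
        for (j in seq(i + 1L, nrow(p))) {
          if (p$x0[i] < p$x1[j] && p$x0[j] < p$x1[i] &&
              p$y0[i] < p$y1[j] && p$y0[j] < p$y1[i])
            return(sprintf("plots %s and %s overlap", p$plot_id[i],
                           p$plot_id[j]))
        }
      }
    }
    TRUE
  })

#' GroundTruth: everything the synthetic renderer knows
#'
#' Per-pixel true abundances, per-plot true mean abundances and noiseless
#' mixed reflectance, true yields, the true calibration gain/bias and the
#' endmember library used, so every downstream stage can be checked against
#' what actually generated the scene.
#'
#' @slot abundances numeric array, rows x cols x 5 true abundances.
#' @slot plotAbundances numeric matrix, plots x 5, pixelwise ROI means.
#' @slot plotReflectance numeric matrix, plots x 6 noiseless mixed
#'   reflectance of the plot-mean abundance.
#' @slot yields numeric, named per-plot yields (kg/ha); empty until generated.
#' @slot gains,biases numeric, the true rendering gain/bias per band.
#' @slot library the \linkS4class{EndmemberLibrary} used for mixing.
#' @aliases GroundTruth
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(abundances = "array", plotAbundances = "matrix",
                 plotReflectance = "matrix", yields = "numeric",
                 gains = "numeric", biases = "numeric",
                 library = "EndmemberLibrary"))

#' CrossValReport: averaged leave-one-out cross-validation results
#'
#' One row of averaged coefficients and accuracy metrics (slope, intercept,
#' R-squared averaged over folds; RMSE from the held-out errors; CV as
#' percent RMSE of mean yield) plus the complete per-fold record.
#'
#' @slot summary one-row data.frame: slope, intercept, r2, rmse, cv, k.
#' @slot folds data.frame with one row per fold: fold, held_out, slope,
#'   intercept, r2, error (observed minus predicted for the held-out sample).
#' @aliases CrossValReport
#' @exportClass CrossValReport
setClass("CrossValReport",
  representation(summary = "data.frame", folds = "data.frame"),
  validity = function(object) {
    if (nrow(object@summary) != 1L) return("summary must have one row")
    if (nrow(object@folds) != object@summary$k)
      return("exactly k folds required")
    if (anyDuplicated(object@folds$held_out))
      return("every sample must be held out exactly once")
    TRUE
  })
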