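#' Mean over a rectangular plot region of interest
#'
#' Unweighted arithmetic mean of every pixel inside the half-open rectangle
#' [x0, x1) x [y0, y1) (0-based, x = column, y = row), per band or channel.
#'
#' @param x a \linkS4class{SpectralImage}, \linkS4class{AbundanceMap} or a
#'   plain numeric matrix (single channel).
#' @param roi list or one-row data.frame with x0, y0, x1, y1.
#' @return named numeric mean vector with attribute \code{pixelCount}.
#' @export
aggregateROI <- function(x, roi) {
  arr <- if (is(x, "SpectralImage") || is(x, "AbundanceMap")) {
    imageData(x)
  } else if (is.matrix(x)) {
    array(x, dim = c(dim(x), 1L))
  } else stopf("unsupported input for aggregateROI")
  d <- dim(arr)
  if (roi$x1 <= roi$x0 || roi$y1 <= roi$y0)
    stopf("roi error: empty rectangle [%g,%g) x [%g,%g)",
          roi$x0, roi$x1, roi$y0, roi$y1)
  if (roi$x0 < 0 || roi$y0 < 0 || roi$x1 > d[2] || roi$y1 > d[1])
    stopf("roi error: rectangle [%g,%g) x [%g,%g) outside %d x %d image",
          roi$x0, roi$x1, roi$y0, roi$y1, d[2], d[1])
  rows <- roiRows(roi); cols <- roiCols(roi)
  m <- vapply(seq_len(d[3]),
              function(k) mean(arr[rows, cols, k]), numeric(1))
  names(m) <- if (is(x, "SpectralImage")) as.character(bandCenters(x))
              else if (is(x, "AbundanceMap")) endmemberNames(x)
  attr(m, "pixelCount") <- length(rows) * length(cols)
  m
}

#' Assemble the per-plot analysis table
#'
#' For every plot ROI: the mean reflectance vector, the ten vegetation
#' indices (computed from the mean reflectance -- the "VI of mean"
#' convention; set \code{viStat = "mean-of-vi"} to average per-pixel VI
#' instead), the mean abundance five-vector, and the joined yield.
#'
#' @param reflImage a reflectance \linkS4class{SpectralImage}.
#' @param abundanceMap an \linkS4class{AbundanceMap} on the same grid.
#' @param rois data.frame: plot_id, n_rate, x0, y0, x1, y1.
#' @param yields optional named numeric vector or data.frame (plot_id,
#'   yield_kg_ha); every plot must have a yield when supplied.
#' @param L SAVI soil factor.
#' @param viStat "vi-of-mean" (default) or "mean-of-vi".
#' @return data.frame with one row per plot: plot_id, n_rate, rho_*, the ten
#'   indices (lower-case columns), abd_*, yield_kg_ha (NA when no yields).
#' @export
buildPlotTable <- function(reflImage, abundanceMap, rois, yields = NULL,
                           L = 0.5, viStat = c("vi-of-mean", "mean-of-vi")) {
  viStat <- match.arg(viStat)
  stopifnot(is(reflImage, "SpectralImage"), is(abundanceMap, "AbundanceMap"))
  if (!all(dim(reflImage)[1:2] == dim(abundanceMap)[1:2]))
    stopf("reflectance image and abundance map are not co-registered")
  if (is.data.frame(yields))
    yields <- stats::setNames(yields$yield_kg_ha, yields$plot_id)
  viCols <- c(NDVI = "ndvi", CIrededge = "ci_rededge", CIgreen = "ci_green",
              VARI = "vari", RVI = "rvi", DVI = "dvi", RDVI = "rdvi",
              EVI = "evi", TVI = "tvi", SAVI = "savi")
  abCols <- c(`FL` = "abd_fl", `SE-LF` = "abd_se_lf", `SS-LF` = "abd_ss_lf",
              `W-soil` = "abd_w_soil", `D-soil` = "abd_d_soil")
  rows <- lapply(seq_len(nrow(rois)), function(i) {
    roi <- rois[i, ]
    refl <- aggregateROI(reflImage, roi)
    ab <- aggregateROI(abundanceMap, roi)
    vi <- if (viStat == "vi-of-mean") {
      vapply(viNames, function(nm) computeVI(nm, refl, L)$value, numeric(1))
    } else {
      vapply(viNames, function(nm) {
        R <- pixelMatrix(imageData(reflImage)[roiRows(roi), roiCols(roi), ,
                                              drop = FALSE])
        mean(.viCore(nm, R, L)$values)
      }, numeric(1))
    }
    y <- NA_real_
    if (!is.null(yields)) {
      if (!roi$plot_id %in% names(yields))
        stopf("join error: no yield for plot id '%s'", roi$plot_id)
      y <- unname(yields[roi$plot_id])
    }
    out <- data.frame(plot_id = roi$plot_id, n_rate = roi$n_rate)
    for (b in seq_along(refl))
      out[[paste0("rho_", names(refl)[b])]] <- unname(refl[b])
    for (nm in viNames) out[[viCols[nm]]] <- unname(vi[nm])
    for (nm in names(abCols)) out[[abCols[nm]]] <- unname(ab[nm])
    out$yield_kg_ha <- y
    out
  })
  do.call(rbind, rows)
}

#' Largest axis-aligned rectangle inscribed in a plot mask
#'
#' Optional helper for users who want the "maximum fitted rectangle"
#' behaviour instead of supplying ROIs explicitly: finds the axis-aligned
#' rectangle of maximal area whose pixels are all TRUE in the mask.
#' Classic largest-rectangle-in-histogram scan over rows.
#'
#' @param mask logical matrix (TRUE = plot pixel).
#' @return list x0, y0, x1, y1 in 0-based half-open pixel coordinates.
#' @export
inscribeMaxRectangle <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  heights <- integer(nc)
  best <- list(area = 0L, x0 = 0L, y0 = 0L, x1 = 0L, y1 = 0L)
  for (r in seq_len(nr)) {
    heights <- ifelse(mask[r, ], heights + 1L, 0L)
    # largest rectangle in histogram via stack scan
    stack <- integer(0); starts <- integer(0)
    for (c in seq_len(nc + 1L)) {
      h <- if (c <= nc) heights[c] else 0L
      start <- c
      while (length(stack) && stack[length(stack)] > h) {
        hh <- stack[length(stack)]; ss <- starts[length(starts)]
        stack <- stack[-length(stack)]; starts <- starts[-length(starts)]
        area <- hh * (c - ss)
        if (area > best$area)
          best <- list(area = area, x0 = ss - 1L, y0 = r - hh,
                       x1 = c - 1L, y1 = r)
        start <- ss
      }
      if (h > 0L && (!length(stack) || stack[length(stack)] < h)) {
        stack <- c(stack, h); starts <- c(starts, start)
      }
    }
  }
  best[c("x0", "y0", "x1", "y1")]
}
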