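#' Ordinary least-squares yield fit
#'
#' Fits yield = slope * x + intercept and reports R-squared
#' (1 - SSres/SStot), RMSE (sqrt(SSres/K)) and CV (100 * RMSE / mean(y), the
#' relative RMSE conventional in yield-estimation work).
#'
#' @param x predictor values (a VI or VI-by-abundance product).
#' @param y observed yields (kg/ha).
#' @return list of class \code{FitResult}: slope, intercept, r2, rmse, cv, k.
#' @export
fitLinearYield <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  k <- length(y)
  if (k < 3L) stopf("need at least 3 samples, got %d", k)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stopf("non-finite values in predictor or yield")
  if (stats::sd(x) == 0) stopf("degenerate predictor: x is constant")
  if (mean(y) == 0) stopf("CV undefined: mean yield is zero")
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  intercept <- yb - slope * xb
  res <- y - (slope * x + intercept)
  ssres <- sum(res^2)
  sstot <- sum((y - yb)^2)
  rmse <- sqrt(ssres / k)
  structure(list(slope = slope, intercept = intercept,
                 r2 = 1 - ssres / sstot, rmse = rmse,
                 cv = 100 * rmse / yb, k = k),
            class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf(
    "yield = %.4g * x + %.4g  (K = %d, R2 = %.3f, RMSE = %.1f kg/ha, CV = %.1f%%)\n",
    x$slope, x$intercept, x$k, x$r2, x$rmse, x$cv))
  invisible(x)
}

#' Averaged leave-one-out cross-validation
#'
#' For each of the K folds, fits the K-1 remaining samples by OLS, records
#' the training coefficients and training R-squared, and the held-out error
#' E_i = y_i - yhat_i. The report averages slope, intercept and R-squared
#' over folds, takes RMSE = sqrt(mean(E_i^2)) from the held-out errors and
#' CV = 100 * RMSE / mean(y). Deterministic: LOOCV involves no randomness.
#'
#' @param x predictor values.
#' @param y observed yields (kg/ha).
#' @param ids optional sample identifiers for the per-fold records.
#' @return A \linkS4class{CrossValReport}.
#' @export
loocvYield <- function(x, y, ids = NULL) {
  k <- length(y)
  if (k < 4L) stopf("LOOCV needs K >= 4, got %d", k)
  if (is.null(ids)) ids <- as.character(seq_len(k))
  folds <- vector("list", k)
  for (i in seq_len(k)) {
    fit <- tryCatch(fitLinearYield(x[-i], y[-i]),
                    error = function(e) stopf("fold %d: %s", i,
                                              conditionMessage(e)))
    pred <- fit$slope * x[i] + fit$intercept
    folds[[i]] <- data.frame(fold = i, held_out = ids[i],
                             slope = fit$slope, intercept = fit$intercept,
                             r2 = fit$r2, error = y[i] - pred)
  }
  folds <- do.call(rbind, folds)
  rmse <- sqrt(mean(folds$error^2))
  summ <- data.frame(slope = mean(folds$slope),
                     intercept = mean(folds$intercept),
                     r2 = mean(folds$r2), rmse = rmse,
                     cv = 100 * rmse / mean(y), k = k)
  new("CrossValReport", summary = summ, folds = folds)
}

# Predictor families: column construction from a plot table.
.familyNames <- c("VI", "VIxFL", "VIxLEAF", "VIxSS")

.familyPredictor <- function(table, viCol, family) {
  vi <- table[[viCol]]
  switch(family,
         VI = vi,
         VIxFL = vi * table$abd_fl,
         VIxLEAF = vi * (table$abd_se_lf + table$abd_ss_lf),
         VIxSS = vi * table$abd_ss_lf,
         stopf("unknown predictor family '%s'", family))
}

.viColumn <- function(name) {
  c(NDVI = "ndvi", CIrededge = "ci_rededge", CIgreen = "ci_green",
    VARI = "vari", RVI = "rvi", DVI = "dvi", RDVI = "rdvi", EVI = "evi",
    TVI = "tvi", SAVI = "savi")[[.matchVI(name)]]
}

#' Evaluate all predictor families against yield
#'
#' Computes the full-sample OLS fit for every combination of the ten
#' vegetation indices and the four predictor families (yield vs VI, VI x
#' flower abundance, VI x total leaf abundance, VI x short-stalk-leaf
#' abundance): 40 fits. For the shortlist of indices, additionally runs
#' averaged leave-one-out cross-validation of the VI x short-stalk-leaf
#' predictor. R-squared values are descriptive (no multiple-testing
#' correction is applied, and full-sample and cross-validated metrics are
#' labelled separately).
#'
#' @param table plot table from \code{\link{buildPlotTable}} with yields.
#' @param shortlist indices to cross-validate (default NDVI, CIrededge, TVI,
#'   SAVI).
#' @return list: \code{fits} (40-row data.frame: vi, family, slope,
#'   intercept, r2, rmse, cv), \code{loocv} (one row per shortlist index:
#'   vi, family, slope, intercept, r2, rmse, cv, k) and \code{loocvReports}
#'   (named list of \linkS4class{CrossValReport}).
#' @export
evaluateAll <- function(table,
                        shortlist = c("NDVI", "CIrededge", "TVI", "SAVI")) {
  need <- c(vapply(viNames, .viColumn, character(1)),
            "abd_fl", "abd_se_lf", "abd_ss_lf", "yield_kg_ha")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stopf("missing column(s) in plot table: %s", paste(miss, collapse = ", "))
  if (anyNA(table$yield_kg_ha)) stopf("missing yields in plot table")
  y <- table$yield_kg_ha
  fits <- do.call(rbind, lapply(viNames, function(nm) {
    viCol <- .viColumn(nm)
    do.call(rbind, lapply(.familyNames, function(fam) {
      f <- fitLinearYield(.familyPredictor(table, viCol, fam), y)
      data.frame(vi = nm, family = fam, slope = f$slope,
                 intercept = f$intercept, r2 = f$r2, rmse = f$rmse,
                 cv = f$cv)
    }))
  }))
  reports <- lapply(shortlist, function(nm) {
    loocvYield(.familyPredictor(table, .viColumn(nm), "VIxSS"), y,
               ids = table$plot_id)
  })
  names(reports) <- vapply(shortlist, .matchVI, character(1))
  loocv <- do.call(rbind, lapply(names(reports), function(nm) {
    cbind(data.frame(vi = nm, family = "VIxSS"), reports[[nm]]@summary)
  }))
  list(fits = fits, loocv = loocv, loocvReports = reports)
}
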