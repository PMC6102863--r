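#' Run the whole analysis pipeline
#'
#' Orchestrates the end-to-end run: synthesize (or ingest) a six-band DN
#' image with calibration panels, fit the empirical line and calibrate to
#' reflectance, unmix against the endmember library, aggregate reflectance
#' and abundances to plot level, and fit the yield models with averaged
#' leave-one-out cross-validation. Writes \code{refl.bsq/.hdr},
#' \code{abund.bsq/.hdr} (plus \code{abund_residual}), \code{plot_table.csv},
#' \code{fits.csv}, \code{loocv.csv}, \code{loocv_folds.csv} and
#' \code{manifest.json} into \code{outDir}.
#'
#' In synthetic mode, supply \code{config}; in ingest mode, supply
#' \code{paths}, a list with elements \code{image} (ENVI base path),
#' \code{panels}, \code{endmembers}, \code{rois}, \code{yields} (CSV paths).
#'
#' @param config a \linkS4class{SceneConfig} for synthetic mode (exclusive
#'   with \code{paths}).
#' @param paths list of input paths for ingest mode.
#' @param outDir output directory.
#' @param L SAVI soil factor.
#' @param shortlist vegetation indices to cross-validate.
#' @param library endmember library for synthetic mode.
#' @return invisibly, a list with the plot table, the evaluation report and
#'   the manifest.
#' @export
runPipeline <- function(config = NULL, paths = NULL, outDir, L = 0.5,
                        shortlist = c("NDVI", "CIrededge", "TVI", "SAVI"),
                        library = defaultEndmemberLibrary()) {
  if (is.null(config) == is.null(paths))
    stopf("supply exactly one of config (synthetic mode) or paths (ingest mode)")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(mode = if (is.null(paths)) "synthetic" else "ingest",
                   package_version = as.character(utils::packageVersion("rapemix")),
                   r_version = as.character(getRversion()))

  if (is.null(paths)) {
    scene <- synthesizeScene(config, library)
    writeScene(scene, outDir)
    dnImage <- scene$image
    panels <- scene$panels
    rois <- scene$rois
    yields <- scene$yields
    lib <- scene$library
    manifest$seed <- config@seed
    manifest$config_hash <- .configHash(config)
  } else {
    for (p in c("image", "panels", "endmembers", "rois", "yields")) {
      if (is.null(paths[[p]]))
        stopf("ingest mode needs paths$%s", p)
      probe <- if (p == "image") paste0(paths[[p]], ".hdr") else paths[[p]]
      if (!file.exists(probe))
        stopf("missing input file for '%s': %s", p, probe)
    }
    dnImage <- readENVI(paths$image)
    panels <- utils::read.csv(paths$panels)
    lib <- readEndmemberCSV(paths$endmembers)
    rois <- readROICSV(paths$rois)
    yields <- readYieldCSV(paths$yields)
  }

  model <- fitEmpiricalLine(panels)
  refl <- applyCalibration(dnImage, model)
  manifest$pixels <- prod(dim(refl)[1:2])
  manifest$out_of_range_pixels <- attr(refl, "outOfRange")
  writeENVI(refl, file.path(outDir, "refl"))

  abund <- unmixImage(refl, lib)
  writeENVI(SpectralImage(imageData(abund),
                          seq_len(length(endmemberNames(abund))),
                          "reflectance"),
            file.path(outDir, "abund"))
  utils::write.csv(data.frame(mean_rms_residual = mean(residualMap(abund))),
                   file.path(outDir, "abund_residual.csv"), row.names = FALSE)

  table <- buildPlotTable(refl, abund, rois, yields, L = L)
  utils::write.csv(table, file.path(outDir, "plot_table.csv"),
                   row.names = FALSE)
  manifest$plots <- nrow(table)

  report <- evaluateAll(table, shortlist = shortlist)
  utils::write.csv(report$fits, file.path(outDir, "fits.csv"),
                   row.names = FALSE)
  utils::write.csv(report$loocv, file.path(outDir, "loocv.csv"),
                   row.names = FALSE)
  folds <- do.call(rbind, lapply(names(report$loocvReports), function(nm)
    cbind(data.frame(vi = nm), report$loocvReports[[nm]]@folds)))
  utils::write.csv(folds, file.path(outDir, "loocv_folds.csv"),
                   row.names = FALSE)

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(table = table, report = report, manifest = manifest,
                 model = model, abundance = abund))
}

# Stable hash of the scene configuration for the manifest.
.configHash <- function(config) {
  s <- paste(utils::capture.output(str(config)), collapse = "\n")
  # small rolling hash; avoids a digest dependency
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}
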