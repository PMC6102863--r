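# File formats. Rasters go out as ENVI BSQ (flat little-endian binary plus a
# text header) because that is the one raster format writable without a
# dedicated geospatial package; tables are plain CSV. All pixel coordinates
# in CSV files are 0-based half-open, x = column, y = row.

#' Write a SpectralImage as an ENVI BSQ raster
#'
#' Band-sequential 64-bit little-endian floats with a standard ENVI text
#' header carrying the band wavelengths and the image unit.
#'
#' @param image a \linkS4class{SpectralImage}.
#' @param base path without extension; writes \code{base.bsq} and
#'   \code{base.hdr}.
#' @return invisibly, the two paths written.
#' @export
writeENVI <- function(image, base) {
  stopifnot(is(image, "SpectralImage"))
  v <- imageData(image)
  d <- dim(v)
  bsq <- paste0(base, ".bsq"); hdr <- paste0(base, ".hdr")
  con <- file(bsq, "wb")
  on.exit(close(con))
  for (b in seq_len(d[3]))                       # BSQ: band, then row-major
    writeBin(as.numeric(t(v[, , b])), con, size = 8, endian = "little")
  writeLines(c(
    "ENVI",
    "description = {rapemix spectral image}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    sprintf("wavelength units = nm"),
    sprintf("wavelength = {%s}",
            paste(bandCenters(image), collapse = ", ")),
    sprintf("rapemix unit = %s", imageUnit(image))), hdr)
  invisible(c(bsq, hdr))
}

.hdrValue <- function(lines, key) {
  ln <- grep(paste0("^", key, "\\s*="), lines, value = TRUE)
  if (!length(ln)) return(NULL)
  trimws(sub("^[^=]*=", "", ln[1]))
}

#' Read an ENVI BSQ raster written by \code{\link{writeENVI}}
#'
#' @param base path without extension (expects \code{base.bsq} and
#'   \code{base.hdr}).
#' @return a \linkS4class{SpectralImage}.
#' @export
readENVI <- function(base) {
  hdr <- readLines(paste0(base, ".hdr"))
  ns <- as.integer(.hdrValue(hdr, "samples"))
  nl <- as.integer(.hdrValue(hdr, "lines"))
  nb <- as.integer(.hdrValue(hdr, "bands"))
  if (.hdrValue(hdr, "data type") != "5" ||
      tolower(.hdrValue(hdr, "interleave")) != "bsq")
    stopf("only data type 5 (double) BSQ ENVI files are supported")
  wl <- .hdrValue(hdr, "wavelength")
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl), ",")[[1]])
  unit <- .hdrValue(hdr, "rapemix unit")
  if (is.null(unit)) unit <- "DN"
  con <- file(paste0(base, ".bsq"), "rb")
  on.exit(close(con))
  v <- array(NA_real_, dim = c(nl, ns, nb))
  for (b in seq_len(nb))
    v[, , b] <- t(matrix(readBin(con, "numeric", ns * nl, size = 8,
                                 endian = "little"), nrow = ns))
  SpectralImage(v, wl, unit)
}

#' Write the endmember library as long-format CSV
#'
#' Columns: endmember, band_nm, reflectance.
#' @param lib an \linkS4class{EndmemberLibrary}.
#' @param path output CSV path.
#' @export
writeEndmemberCSV <- function(lib, path) {
  m <- spectra(lib)
  df <- data.frame(
    endmember = rep(colnames(m), each = nrow(m)),
    band_nm = rep(bandCenters(lib), ncol(m)),
    reflectance = as.vector(m))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an endmember library CSV (endmember, band_nm, reflectance)
#'
#' @param path CSV path.
#' @return an \linkS4class{EndmemberLibrary}.
#' @export
readEndmemberCSV <- function(path) {
  df <- utils::read.csv(path)
  need <- c("endmember", "band_nm", "reflectance")
  if (!all(need %in% names(df)))
    stopf("endmember CSV must have columns %s", paste(need, collapse = ", "))
  bands <- sort(unique(df$band_nm))
  ems <- unique(df$endmember)
  m <- matrix(NA_real_, length(bands), length(ems),
              dimnames = list(as.character(bands), ems))
  for (i in seq_len(nrow(df)))
    m[as.character(df$band_nm[i]), df$endmember[i]] <- df$reflectance[i]
  if (anyNA(m)) stopf("endmember CSV is incomplete")
  EndmemberLibrary(m, bands)
}

#' Write all artifacts of a synthetic scene to a directory
#'
#' Writes the DN image (\code{dn.bsq/.hdr}), \code{panels.csv},
#' \code{rois.csv}, \code{yields.csv}, \code{endmembers.csv} and a
#' \code{truth.json} ground-truth sidecar (calibration gains/biases, per-plot
#' true abundances and yields; the per-pixel truth stays in memory).
#'
#' @param scene list from \code{\link{synthesizeScene}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeENVI(scene$image, file.path(dir, "dn"))
  utils::write.csv(scene$panels, file.path(dir, "panels.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$rois, file.path(dir, "rois.csv"), row.names = FALSE)
  utils::write.csv(data.frame(plot_id = names(scene$yields),
                              yield_kg_ha = unname(scene$yields)),
                   file.path(dir, "yields.csv"), row.names = FALSE)
  writeEndmemberCSV(scene$library, file.path(dir, "endmembers.csv"))
  truth <- scene$truth
  jsonlite::write_json(list(
    gains = truth@gains, biases = truth@biases,
    band_nm = bandCenters(scene$library),
    plot_abundances = as.data.frame(truth@plotAbundances),
    plot_ids = rownames(truth@plotAbundances),
    yields = unname(truth@yields), seed = scene$config@seed),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read plot ROI definitions (plot_id, n_rate, x0, y0, x1, y1)
#' @param path CSV path.
#' @return data.frame.
#' @export
readROICSV <- function(path) {
  df <- utils::read.csv(path)
  need <- c("plot_id", "x0", "y0", "x1", "y1")
  if (!all(need %in% names(df)))
    stopf("ROI CSV must have columns %s", paste(need, collapse = ", "))
  if (!"n_rate" %in% names(df)) df$n_rate <- NA_real_
  df
}

#' Read a yields CSV (plot_id, yield_kg_ha)
#' @param path CSV path.
#' @return named numeric vector.
#' @export
readYieldCSV <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("plot_id", "yield_kg_ha") %in% names(df)))
    stopf("yield CSV must have columns plot_id, yield_kg_ha")
  stats::setNames(df$yield_kg_ha, df$plot_id)
}
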