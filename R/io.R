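## File-format round trips: 8-bit grayscale PNG/TIFF images, boundary and
## cohort CSVs, ground-truth / QC / manifest JSON.

.COHORT_MANDATORY <- c("subject_id", "age", "sex", "se", "bcva", "al",
                       "iop", "vf_md", "rpe_gray", "imageq", "laterality")

#' Read a B-scan image file
#'
#' Reads an 8-bit grayscale PNG or TIFF; color images are collapsed to
#' grayscale by channel averaging. Intensities are returned on the 0-255
#' scale.
#'
#' @param path image file (`.png`, `.tif`/`.tiff`).
#' @param axialScale axial micrometers per pixel of the scan.
#' @param laterality `"OD"` or `"OS"`.
#' @param qualityFactor optional known quality value.
#' @return a [BScanImage-class].
#' @export
readBScan <- function(path, axialScale = 5, laterality = "OD",
                      qualityFactor = NA_real_) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext))
  )
  if (length(dim(arr)) == 3) arr <- apply(arr[, , 1:min(3, dim(arr)[3]),
                                              drop = FALSE], c(1, 2), mean)
  new("BScanImage", pixels = round(arr * 255), axialScale = axialScale,
      laterality = laterality, qualityFactor = qualityFactor)
}

#' Write a B-scan as 8-bit grayscale PNG
#'
#' PNG is lossless, so a write/read round trip reproduces the pixel grid
#' exactly.
#'
#' @param image a [BScanImage-class].
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
writeBScan <- function(image, path) {
  stopifnot(is(image, "BScanImage"))
  png::writePNG(image@pixels / 255, path)
  invisible(path)
}

#' Write / read boundary traces as CSV
#'
#' Columns: `column_index, ilm, rnfl_post, rpe_inner, rpe_outer`.
#'
#' @param boundaries a [LayerBoundaries-class].
#' @param path CSV path.
#' @return `path` (write) or a [LayerBoundaries-class] (read).
#' @export
writeBoundaries <- function(boundaries, path) {
  stopifnot(is(boundaries, "LayerBoundaries"))
  df <- data.frame(column_index = seq_along(boundaries@ilm),
                   ilm = boundaries@ilm, rnfl_post = boundaries@rnflPost,
                   rpe_inner = boundaries@rpeInner,
                   rpe_outer = boundaries@rpeOuter)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBoundaries
#' @export
readBoundaries <- function(path) {
  df <- read.csv(path)
  new("LayerBoundaries", ilm = df$ilm, rnflPost = df$rnfl_post,
      rpeInner = df$rpe_inner, rpeOuter = df$rpe_outer)
}

#' Write / read a ground-truth sidecar as JSON
#'
#' @param truth a [GroundTruth-class].
#' @param path JSON path.
#' @return `path` (write) or a [GroundTruth-class] (read).
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  jsonlite::write_json(
    list(ilm = truth@ilm, rnfl_post = truth@rnflPost,
         rpe_inner = truth@rpeInner, rpe_outer = truth@rpeOuter,
         rnfl_refl = truth@rnflRefl, rpe_refl = truth@rpeRefl),
    path, digits = NA)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("GroundTruth", ilm = x$ilm, rnflPost = x$rnfl_post,
      rpeInner = x$rpe_inner, rpeOuter = x$rpe_outer,
      rnflRefl = x$rnfl_refl, rpeRefl = x$rpe_refl)
}

#' Write a QC report as JSON
#'
#' @param qc a [QCReport-class].
#' @param path JSON path.
#' @export
writeQCReport <- function(qc, path) {
  stopifnot(is(qc, "QCReport"))
  jsonlite::write_json(
    list(misidentification = qc@misidentification, reasons = qc@reasons,
         scores = as.list(qc@scores)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort CSV
#'
#' Validates the documented schema (`subject_id, age, sex, se, bcva, al,
#' iop, vf_md, rpe_gray, imageq, laterality`, plus any `true_`-prefixed
#' truth, measurement or flag columns, which are preserved as is). A
#' missing mandatory column raises a schema error naming it.
#'
#' @param path cohort CSV path.
#' @return data.frame with all columns preserved.
#' @export
readCohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.COHORT_MANDATORY, names(df))
  if (length(missing))
    stop(sprintf("cohort CSV is missing mandatory column(s): %s",
                 paste(missing, collapse = ", ")))
  df
}

#' Write a cohort CSV
#'
#' @param cohort cohort data.frame.
#' @param path output CSV path.
#' @export
writeCohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
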