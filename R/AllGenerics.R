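#' @rdname BScanImage-class
#' @param object,x a package object.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname BScanImage-class
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))

#' @rdname BScanImage-class
#' @export
setGeneric("axialScale", function(x) standardGeneric("axialScale"))

#' @rdname BScanImage-class
#' @export
setGeneric("laterality", function(x) standardGeneric("laterality"))

#' @rdname BScanImage-class
#' @export
setGeneric("qualityFactor", function(x) standardGeneric("qualityFactor"))

#' @rdname LayerBoundaries-class
#' @export
setGeneric("boundaryTrace", function(x, which) standardGeneric("boundaryTrace"))

#' @rdname QCReport-class
#' @export
setGeneric("isMisidentified", function(x) standardGeneric("isMisidentified"))

#' @describeIn BScanImage-class pixel matrix accessor.
setMethod("pixels", "BScanImage", function(x) x@pixels)

#' @describeIn BScanImage-class number of A-scan columns.
setMethod("nColumns", "BScanImage", function(x) ncol(x@pixels))

#' @describeIn BScanImage-class axial scale in micrometers per pixel.
setMethod("axialScale", "BScanImage", function(x) x@axialScale)

#' @describeIn BScanImage-class eye laterality, `"OD"` or `"OS"`.
setMethod("laterality", "BScanImage", function(x) x@laterality)

#' @describeIn BScanImage-class quality value carried with the image.
setMethod("qualityFactor", "BScanImage", function(x) x@qualityFactor)

#' @describeIn LayerBoundaries-class extract one trace by name
#'   (`"ilm"`, `"rnflPost"`, `"rpeInner"`, `"rpeOuter"`).
#' @param which trace name.
setMethod("boundaryTrace", "LayerBoundaries", function(x, which) {
  which <- match.arg(which, c("ilm", "rnflPost", "rpeInner", "rpeOuter"))
  slot(x, which)
})

#' @describeIn QCReport-class `TRUE` if any QC rule fired.
setMethod("isMisidentified", "QCReport", function(x) x@misidentification)

setMethod("show", "BScanImage", function(object) {
  cat(sprintf(
    "BScanImage: %d x %d pixels (%s), %.3g um/px axial, %.3g mm circle%s\n",
    nrow(object@pixels), ncol(object@pixels), object@laterality,
    object@axialScale, object@scanDiameter,
    if (is.na(object@qualityFactor)) "" else
      sprintf(", quality %.1f", object@qualityFactor)))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "LayerBoundaries", function(object) {
  cat(sprintf("LayerBoundaries over %d columns\n", length(object@ilm)))
  for (tr in c("ilm", "rnflPost", "rpeInner", "rpeOuter"))
    cat(sprintf("  %-8s rows %.1f-%.1f (median %.1f)\n", tr,
                min(slot(object, tr)), max(slot(object, tr)),
                median(slot(object, tr))))
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: %s\n",
              if (object@misidentification) "MISIDENTIFICATION" else "pass"))
  if (length(object@reasons))
    cat("  reasons:", paste(object@reasons, collapse = ", "), "\n")
  if (length(object@scores))
    cat("  scores:", paste(sprintf("%s=%.3g", names(object@scores),
                                   object@scores), collapse = ", "), "\n")
})

setMethod("show", "SectorScheme", function(object) {
  cat("SectorScheme:\n")
  cat(paste(sprintf("  %-3s [%g, %g) deg", object@labels, object@loDeg,
                    object@hiDeg), collapse = "\n"), "\n")
})

setMethod("show", "PRNFLMeasurement", function(object) {
  cat(sprintf("PRNFLMeasurement: gray %.2f | thickness %.2f um | RPE %.2f | imageq %.1f\n",
              object@grayMean, object@thickMean, object@rpeGray, object@imageq))
  cat("  sector gray: ",
      paste(sprintf("%s=%.2f", names(object@graySector), object@graySector),
            collapse = " "), "\n")
  cat("  sector thickness:",
      paste(sprintf("%s=%.1f", names(object@thickSector), object@thickSector),
            collapse = " "), "\n")
})

setMethod("show", "GenerativeParams", function(object) {
  cat(sprintf(
    "GenerativeParams: gray target %.2f (SD %.2f), %d covariates, seed %d\n",
    object@grayTarget, object@totalGraySD, nrow(object@covariates),
    as.integer(object@seed)))
  act <- object@effects[object@effects != 0]
  cat("  active effects:",
      if (length(act)) paste(sprintf("%s=%.3f", names(act), act),
                             collapse = " ") else "(none)", "\n")
  cat(sprintf("  speckle shape %s, between-eye thickness SD %.2f um\n",
              format(object@speckleShape), object@thickSD))
})
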