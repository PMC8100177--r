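#' @useDynLib pRNFLgray, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot slotNames show
#' @importFrom stats dnorm pnorm qnorm quantile median mad rgamma rnorm runif
#'   lm coef vcov pt t.test sd var complete.cases setNames aggregate
#' @importFrom utils read.csv write.csv head
NULL

## Canonical sector order used everywhere in the package: temporal,
## inferior-temporal, inferior-nasal, nasal, superior-nasal, superior-temporal.
.SECTORS <- c("T", "IT", "IN", "N", "SN", "ST")

#' One circular peripapillary B-scan
#'
#' An 8-bit grayscale raster of a circular (peripapillary) OCT B-scan plus
#' its acquisition metadata. Row 1 is the vitreous side; columns are A-scans
#' in acquisition order around the scan circle.
#'
#' @slot pixels numeric matrix, intensities in \[0, 255\] (0 = pure black,
#'   255 = pure white), rows = depth, columns = A-scans.
#' @slot axialScale axial sampling in micrometers per pixel row.
#' @slot scanDiameter diameter of the scan circle in mm.
#' @slot laterality `"OD"` (right) or `"OS"` (left eye).
#' @slot qualityFactor device or proxy image-quality value (`NA` if unknown).
#'
#' @seealso [bScanImage()], [renderBScan()], [segmentBoundaries()]
#' @export
setClass("BScanImage",
  representation(
    pixels = "matrix",
    axialScale = "numeric",
    scanDiameter = "numeric",
    laterality = "character",
    qualityFactor = "numeric"
  ),
  prototype(
    axialScale = 5,
    scanDiameter = 3.46,
    laterality = "OD",
    qualityFactor = NA_real_
  )
)

setValidity("BScanImage", function(object) {
  p <- object@pixels
  msg <- character()
  if (!is.numeric(p)) msg <- c(msg, "pixels must be a numeric matrix")
  else {
    if (anyNA(p) || min(p) < 0 || max(p) > 255)
      msg <- c(msg, "pixel intensities must lie in [0, 255]")
    if (ncol(p) < 64) msg <- c(msg, "image must have at least 64 columns (A-scans)")
  }
  if (length(object@axialScale) != 1 || !is.finite(object@axialScale) ||
      object@axialScale <= 0)
    msg <- c(msg, "axialScale must be a single positive number")
  if (length(object@laterality) != 1 || !object@laterality %in% c("OD", "OS"))
    msg <- c(msg, "laterality must be \"OD\" or \"OS\"")
  if (length(msg)) msg else TRUE
})

#' Segmented layer boundaries of one B-scan
#'
#' Per-column (fractional) row positions of the internal limiting membrane
#' (`ilm`), the posterior pRNFL boundary (`rnflPost`) and the inner and outer
#' edges of the RPE band. Rows are 1-based; a boundary at row \eqn{u} means
#' the layer below it owns pixel rows `ceiling(u)` onward, i.e. a layer
#' between boundaries `upper` and `lower` owns the half-open pixel band
#' `[ceiling(upper), ceiling(lower))`.
#'
#' @slot ilm,rnflPost,rpeInner,rpeOuter numeric vectors, one entry per
#'   image column, ordered `ilm <= rnflPost <= rpeInner <= rpeOuter`.
#'
#' @seealso [segmentBoundaries()], [measureEye()]
#' @export
setClass("LayerBoundaries",
  representation(
    ilm = "numeric",
    rnflPost = "numeric",
    rpeInner = "numeric",
    rpeOuter = "numeric"
  )
)

setValidity("LayerBoundaries", function(object) {
  n <- length(object@ilm)
  msg <- character()
  if (length(object@rnflPost) != n || length(object@rpeInner) != n ||
      length(object@rpeOuter) != n)
    msg <- c(msg, "all four traces must have the same length")
  else {
    tol <- 1e-9
    if (any(object@rnflPost < object@ilm - tol) ||
        any(object@rpeInner < object@rnflPost - tol) ||
        any(object@rpeOuter < object@rpeInner - tol))
      msg <- c(msg, "traces must satisfy ilm <= rnflPost <= rpeInner <= rpeOuter in every column")
  }
  if (length(msg)) msg else TRUE
})

#' Boundary-misidentification QC report
#'
#' Result of the deterministic quality-control rules applied to a
#' segmentation (see [flagMisidentification()]). `misidentification` is
#' `TRUE` exactly when at least one rule fired.
#'
#' @slot misidentification logical flag.
#' @slot reasons identifiers of the rules that fired (possibly empty).
#' @slot scores named numeric vector with the per-rule statistics.
#' @export
setClass("QCReport",
  representation(
    misidentification = "logical",
    reasons = "character",
    scores = "numeric"
  ),
  prototype(misidentification = FALSE, reasons = character())
)

setValidity("QCReport", function(object) {
  if (object@misidentification != (length(object@reasons) > 0))
    "misidentification must be TRUE iff reasons is nonempty"
  else TRUE
})

#' Six-sector angular scheme of the scan circle
#'
#' Half-open angular sectors, in degrees in the right-eye (OD) frame with
#' the temporal horizontal meridian at 0 and angles increasing through
#' superior: temporal \[315, 45), superior-temporal \[45, 90), superior-nasal
#' \[90, 135), nasal \[135, 225), inferior-nasal \[225, 270),
#' inferior-temporal \[270, 315). Temporal and nasal span 90 degrees, the
#' other four 45 degrees; the six sectors tile \[0, 360) exactly.
#'
#' @slot labels sector labels (canonical order `T, IT, IN, N, SN, ST`).
#' @slot loDeg,hiDeg interval bounds in degrees; an interval with
#'   `lo > hi` wraps through 0 (the temporal sector).
#'
#' @seealso [sectorScheme()], [sectorOfAngle()]
#' @export
setClass("SectorScheme",
  representation(labels = "character", loDeg = "numeric", hiDeg = "numeric")
)

setValidity("SectorScheme", function(object) {
  k <- length(object@labels)
  msg <- character()
  if (length(object@loDeg) != k || length(object@hiDeg) != k)
    msg <- c(msg, "labels, loDeg and hiDeg must have equal length")
  else {
    span <- (object@hiDeg - object@loDeg) %% 360
    if (abs(sum(span) - 360) > 1e-9)
      msg <- c(msg, "sector spans must tile [0, 360) exactly")
    if (anyDuplicated(object@labels)) msg <- c(msg, "sector labels must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct the standard six-sector scheme
#'
#' @return A [SectorScheme-class] with the conventional peripapillary
#'   sectors (temporal and nasal 90 degrees wide, the four oblique sectors 45).
#' @examples
#' sectorOfAngle(180, sectorScheme())  # "N"
#' @export
sectorScheme <- function() {
  new("SectorScheme",
    labels = .SECTORS,
    loDeg = c(315, 270, 225, 135, 90, 45),
    hiDeg = c(45, 315, 270, 225, 135, 90)
  )
}

#' Per-eye pRNFL measurement
#'
#' The measurement bundle produced by [measureEye()]: average and
#' six-sector pRNFL grayscale values (0-255) and thicknesses (micrometers),
#' the RPE-band grayscale reference, an image-quality value, and the QC
#' report of the underlying segmentation.
#'
#' @slot grayMean average pRNFL grayscale value over the full 360 degrees.
#' @slot graySector named numeric (sectors `T, IT, IN, N, SN, ST`).
#' @slot thickMean average pRNFL thickness in micrometers.
#' @slot thickSector named numeric, sector thicknesses in micrometers.
#' @slot rpeGray mean grayscale value of the RPE band.
#' @slot imageq image-quality value (device-supplied or [computeImageQ()]).
#' @slot qc the [QCReport-class] of the segmentation, or `NULL`.
#' @export
setClass("PRNFLMeasurement",
  representation(
    grayMean = "numeric",
    graySector = "numeric",
    thickMean = "numeric",
    thickSector = "numeric",
    rpeGray = "numeric",
    imageq = "numeric",
    qc = "ANY"
  )
)

setValidity("PRNFLMeasurement", function(object) {
  msg <- character()
  g <- c(object@grayMean, object@graySector, object@rpeGray)
  if (any(!is.finite(g)) || any(g < 0) || any(g > 255))
    msg <- c(msg, "grayscale values must lie in [0, 255]")
  th <- c(object@thickMean, object@thickSector)
  if (any(!is.finite(th)) || any(th < 0))
    msg <- c(msg, "thicknesses must be >= 0")
  if (!identical(names(object@graySector), .SECTORS) ||
      !identical(names(object@thickSector), .SECTORS))
    msg <- c(msg, "sector vectors must be named T, IT, IN, N, SN, ST in order")
  if (length(msg)) msg else TRUE
})

#' Ground truth of one rendered B-scan
#'
#' Sidecar produced by [renderBScan()]: the exact (fractional, 1-based)
#' boundary rows and the per-column mean layer reflectivities used during
#' rendering, for oracle comparisons against segmentation output.
#'
#' @slot ilm,rnflPost,rpeInner,rpeOuter exact boundary rows per column.
#' @slot rnflRefl,rpeRefl per-column mean reflectivity (0-255) of the pRNFL
#'   and the RPE band.
#' @export
setClass("GroundTruth",
  representation(
    ilm = "numeric", rnflPost = "numeric",
    rpeInner = "numeric", rpeOuter = "numeric",
    rnflRefl = "numeric", rpeRefl = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  tol <- 1e-9
  if (any(object@rnflPost < object@ilm - tol) ||
      any(object@rpeInner < object@rnflPost - tol) ||
      any(object@rpeOuter < object@rpeInner - tol))
    return("boundaries must satisfy ilm <= rnflPost <= rpeInner <= rpeOuter")
  if (any(object@rnflRefl < 0 | object@rnflRefl > 255) ||
      any(object@rpeRefl < 0 | object@rpeRefl > 255))
    return("reflectivities must lie in [0, 255]")
  TRUE
})

#' Generative parameters of the synthetic cohort
#'
#' Study conditions for the cohort and B-scan generator: covariate
#' truncated-normal moments, the linear determinant model of the average
#' pRNFL grayscale value, per-sector grayscale offsets and thickness means,
#' and the speckle model. Build with [generativeParams()], which installs
#' the normative-scenario defaults.
#'
#' @slot covariates data.frame with columns `name, mean, sd, min, max`
#'   (rows: age, se, bcva, al, iop, vf_md, rpe_gray, imageq).
#' @slot sexPropMale proportion of males (sex coded female = 0, male = 1).
#' @slot effects named slopes (gray levels per covariate unit) of the
#'   linear model for the average grayscale value.
#' @slot grayTarget cohort mean of the average grayscale value; the model
#'   intercept is solved so the (truncated-normal) expectation hits it.
#' @slot totalGraySD target cohort SD of the average grayscale value.
#' @slot residualSD residual SD; `NA` means "solve from the variance
#'   budget": \eqn{\sigma_\epsilon^2 =} `totalGraySD`\eqn{^2 -}
#'   Var(linear predictor).
#' @slot sectorGrayOffsets named additive offsets (gray levels) of each
#'   sector relative to the eye average.
#' @slot sectorThickness named mean sector thicknesses in micrometers.
#' @slot thickSD between-eye SD (micrometers) of the common additive
#'   thickness deviation.
#' @slot speckleShape shape of the unit-mean gamma multiplicative speckle;
#'   `Inf` disables speckle.
#' @slot seed master seed; per-eye seeds derive from it (see
#'   [deriveEyeSeed()]).
#' @seealso [generativeParams()], [sampleCohort()], [renderBScan()]
#' @export
setClass("GenerativeParams",
  representation(
    covariates = "data.frame",
    sexPropMale = "numeric",
    effects = "numeric",
    grayTarget = "numeric",
    totalGraySD = "numeric",
    residualSD = "numeric",
    sectorGrayOffsets = "numeric",
    sectorThickness = "numeric",
    thickSD = "numeric",
    speckleShape = "numeric",
    seed = "numeric"
  )
)

setValidity("GenerativeParams", function(object) {
  msg <- character()
  cv <- object@covariates
  need <- c("name", "mean", "sd", "min", "max")
  if (!all(need %in% names(cv))) {
    msg <- c(msg, "covariates must have columns name, mean, sd, min, max")
    return(msg)
  }
  if (any(cv$sd < 0)) msg <- c(msg, "covariate SDs must be >= 0")
  if (any(cv$min > cv$mean | cv$mean > cv$max))
    msg <- c(msg, "each covariate needs min <= mean <= max")
  if (object@sexPropMale < 0 || object@sexPropMale > 1)
    msg <- c(msg, "sexPropMale must be in [0, 1]")
  if (!identical(names(object@sectorGrayOffsets), .SECTORS) ||
      !identical(names(object@sectorThickness), .SECTORS))
    msg <- c(msg, "sector vectors must be named T, IT, IN, N, SN, ST in order")
  else {
    if (any(object@grayTarget + object@sectorGrayOffsets < 0) ||
        any(object@grayTarget + object@sectorGrayOffsets > 255))
      msg <- c(msg, "sector gray offsets must keep sector means inside [0, 255]")
    if (any(object@sectorThickness <= 0))
      msg <- c(msg, "sector thicknesses must be positive")
  }
  if (!is.na(object@residualSD) && object@residualSD < 0)
    msg <- c(msg, "residualSD must be >= 0 (or NA to solve from the variance budget)")
  if (is.na(object@residualSD) && length(msg) == 0) {
    expl <- .explainedVariance(object)
    if (object@totalGraySD^2 - expl < 0)
      msg <- c(msg, sprintf(
        "variance budget violated: totalGraySD^2 = %.3f is smaller than the variance explained by the effects (%.3f)",
        object@totalGraySD^2, expl))
  }
  if (object@speckleShape <= 0)
    msg <- c(msg, "speckleShape must be positive (Inf disables speckle)")
  if (length(msg)) msg else TRUE
})
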