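## Boundary segmentation of circular B-scans: sequential dynamic-programming
## minimum-cost paths on signed vertical-gradient cost images. The four
## traces are found in the order ILM (strongest dark-to-bright edge),
## RPE inner (dark-to-bright below the ILM), pRNFL posterior
## (bright-to-dark between ILM and RPE inner), RPE outer (bright-to-dark
## below RPE inner), each restricted to the band admissible after the
## previously found traces, which guarantees the ordering invariant by
## construction. This is a transparent, deterministic stand-in for the
## proprietary segmentation of clinical analysis software; it is not a
## reproduction of any device algorithm.

#' Median-filter a B-scan
#'
#' Square median filter (odd kernel, borders replicated) used as a
#' speckle-robust pre-filter before gradient-based segmentation.
#' `kernel = 1` returns the input unchanged.
#'
#' @param image a [BScanImage-class].
#' @param kernel odd window side length in pixels.
#' @return a filtered [BScanImage-class] (metadata preserved).
#' @export
denoiseBScan <- function(image, kernel = 3) {
  stopifnot(is(image, "BScanImage"))
  if (length(kernel) != 1 || kernel < 1 || kernel %% 2 == 0)
    stop("kernel must be a single odd integer >= 1")
  if (kernel == 1) return(image)
  p <- median_filter_cpp(image@pixels, as.integer(kernel))
  new("BScanImage", pixels = p, axialScale = image@axialScale,
      scanDiameter = image@scanDiameter, laterality = image@laterality,
      qualityFactor = image@qualityFactor)
}

## Quadratic sub-pixel refinement of a gradient peak. The integer DP row r
## is the first pixel row of the deeper layer, so the true boundary lies in
## (r-1, r]; the refined estimate is centered there (r - 0.5) and nudged by
## the vertex of a parabola through the signed gradient at rows
## (r-1, r, r+1), clamped so that ceiling(estimate) stays r and the
## half-open pixel-band convention is preserved.
.subpixelRefine <- function(p, path, sign) {
  H <- nrow(p); W <- ncol(p)
  g <- rbind(0, sign * (p[-1, , drop = FALSE] - p[-H, , drop = FALSE]))
  delta <- numeric(W)
  ok <- path >= 3 & path <= H - 1
  idx <- which(ok)
  if (length(idx)) {
    gm <- g[cbind(path[idx] - 1, idx)]
    g0 <- g[cbind(path[idx], idx)]
    gp <- g[cbind(path[idx] + 1, idx)]
    den <- gm + gp - 2 * g0
    d <- ifelse(den < 0, (gm - gp) / (2 * den), 0)
    delta[idx] <- pmin(pmax(d, -0.45), 0.45)
  }
  path - 0.5 + delta
}

#' Segment the ILM, posterior pRNFL boundary and RPE band
#'
#' Finds four ordered, smooth boundary traces as sequential
#' dynamic-programming minimum-cost paths on the vertical gradient of the
#' (ideally pre-filtered, see [denoiseBScan()]) image. Transitions between
#' adjacent columns are limited to `maxJump` rows and penalised by `lambda`
#' per row; cost ties break toward the smaller (vitread) row, so results
#' are bit-reproducible. Integer paths are refined to fractional rows by
#' quadratic interpolation of the gradient peak.
#'
#' @param image a [BScanImage-class].
#' @param maxJump smoothness bound: maximum row change per column step.
#' @param lambda jump penalty per row of column-to-column jump, in the
#'   cost units of the respective stage (signed gradient for the edge
#'   paths, per-pixel residual variance for the changepoint path).
#' @param minGradient minimum gradient magnitude required anywhere in the
#'   image; below it the scan is considered structureless and a
#'   segmentation-failure error (class `prnflSegmentationFailure`) is
#'   raised, distinguishable from QC flagging.
#' @param minRnflGap minimum ILM-to-RPE separation in micrometers assumed
#'   when restricting the RPE search band.
#' @param maxRpeBand maximum RPE band height in micrometers.
#' @return a [LayerBoundaries-class].
#' @export
segmentBoundaries <- function(image, maxJump = 3, lambda = 20,
                              minGradient = 2, minRnflGap = 40,
                              maxRpeBand = 80) {
  stopifnot(is(image, "BScanImage"))
  p <- image@pixels
  H <- nrow(p); W <- ncol(p)
  grad <- p[-1, , drop = FALSE] - p[-H, , drop = FALSE]
  if (max(abs(grad)) < minGradient)
    stop(errorCondition(
      "no admissible boundary path: image has no intensity structure",
      class = c("prnflSegmentationFailure", "error", "condition")))

  dp <- function(sign, lo, hi) {
    lo <- pmax(pmin(lo, H - 1L), 2L)
    hi <- pmax(pmin(hi, H - 1L), lo)
    dp_edge_path_cpp(p, sign, as.integer(lo) - 1L, as.integer(hi) - 1L,
                     as.integer(maxJump), lambda) + 1L
  }

  gapPx <- as.integer(ceiling(minRnflGap / image@axialScale))
  rpePx <- as.integer(ceiling(maxRpeBand / image@axialScale))

  ilm <- dp(+1, rep(2L, W), rep(H - 2L - 2L * rpePx, W))
  rpeInner <- dp(+1, ilm + gapPx, rep(H - 2L, W))
  # posterior pRNFL boundary: two-segment changepoint cost between the ILM
  # and the RPE inner edge (uses every pixel of the column, robust to
  # speckle outliers that defeat a single-row gradient)
  cpCost <- changepoint_cost_cpp(p, ilm - 1L, rpeInner - 1L)
  rnflPost <- dp_cost_path_cpp(cpCost, ilm - 1L, rpeInner - 1L,
                               as.integer(maxJump), lambda) + 1L
  rpeOuter <- dp(-1, rpeInner + 1L, rpeInner + rpePx)

  ilmF <- .subpixelRefine(p, ilm, +1)
  rpeInnerF <- pmax(.subpixelRefine(p, rpeInner, +1), ilmF)
  rnflPostF <- pmin(pmax(rnflPost - 0.5, ilmF), rpeInnerF)
  rpeOuterF <- pmax(.subpixelRefine(p, rpeOuter, -1), rpeInnerF)

  new("LayerBoundaries", ilm = ilmF, rnflPost = rnflPostF,
      rpeInner = rpeInnerF, rpeOuter = rpeOuterF)
}

#' Flag boundary misidentification
#'
#' Deterministic quality-control rules standing in for the manual
#' inspection of segmented scans used in clinical reading workflows. A
#' segmentation is flagged when any rule fires: (a) the median pRNFL thickness falls outside a plausibility
#' band; (b) any trace is rougher (mean absolute second difference) than a
#' threshold; (c) the mean intensity inside the pRNFL band does not exceed
#' the mean background (vitreous) intensity.
#'
#' @param image a [BScanImage-class].
#' @param boundaries a [LayerBoundaries-class] satisfying the ordering
#'   invariant.
#' @param thicknessBand plausible median pRNFL thickness range, micrometers.
#' @param maxRoughness maximum mean absolute second difference, pixels.
#' @return a [QCReport-class]; never raises an error.
#' @export
flagMisidentification <- function(image, boundaries,
                                  thicknessBand = c(30, 250),
                                  maxRoughness = 2) {
  stopifnot(is(image, "BScanImage"), is(boundaries, "LayerBoundaries"))
  p <- image@pixels
  reasons <- character()

  medThick <- median(boundaries@rnflPost - boundaries@ilm) * image@axialScale
  if (medThick < thicknessBand[1] || medThick > thicknessBand[2])
    reasons <- c(reasons, "thickness_implausible")

  rough <- vapply(c("ilm", "rnflPost", "rpeInner", "rpeOuter"),
                  function(tr) mean(abs(diff(slot(boundaries, tr),
                                             differences = 2))),
                  numeric(1))
  if (max(rough) > maxRoughness) reasons <- c(reasons, "trace_rough")

  a <- ceiling(boundaries@ilm); b <- ceiling(boundaries@rnflPost)
  layerSum <- 0; layerN <- 0L; bgSum <- 0; bgN <- 0L
  for (c in seq_len(ncol(p))) {
    if (b[c] > a[c]) {
      layerSum <- layerSum + sum(p[a[c]:(b[c] - 1), c])
      layerN <- layerN + (b[c] - a[c])
    }
    top <- max(a[c] - 3L, 1L)
    if (top > 1L) {
      bgSum <- bgSum + sum(p[1:(top - 1L), c])
      bgN <- bgN + (top - 1L)
    }
  }
  layerMean <- if (layerN > 0) layerSum / layerN else NA_real_
  bgMean <- if (bgN > 0) bgSum / bgN else NA_real_
  contrast <- layerMean - bgMean
  if (!is.na(contrast) && contrast <= 0)
    reasons <- c(reasons, "layer_darker_than_background")

  new("QCReport", misidentification = length(reasons) > 0,
      reasons = reasons,
      scores = c(median_thickness_um = medThick,
                 max_roughness_px = max(rough),
                 layer_minus_background = contrast))
}
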