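## Synthetic cohort + B-scan generator. The generator's defaults are the
## a normative-cohort scenario: covariate moments typical of a 397-eye
## adult normative sample, the linear determinant structure of the
## average pRNFL grayscale value, and the sectoral grayscale/thickness
## pattern of its Total row. Speckle is unit-mean multiplicative gamma.

#' Moments of a truncated normal distribution
#'
#' Mean and variance of \eqn{N(\mu, \sigma^2)} truncated to \eqn{[a, b]},
#' by the standard closed form. Used both to sample covariates (inverse-CDF)
#' and to solve the generator's variance budget analytically.
#'
#' @param mean,sd moments of the parent normal (`sd >= 0`).
#' @param min,max truncation bounds.
#' @return list with elements `mean` and `var`.
#' @export
truncNormMoments <- function(mean, sd, min, max) {
  if (sd == 0) return(list(mean = mean, var = 0))
  a <- (min - mean) / sd
  b <- (max - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  da <- dnorm(a); db <- dnorm(b)
  m <- mean + sd * (da - db) / Z
  v <- sd^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  list(mean = m, var = v)
}

## Variance of the linear predictor under independent covariates.
.explainedVariance <- function(params) {
  cv <- params@covariates
  v <- 0
  for (i in seq_len(nrow(cv))) {
    beta <- params@effects[[cv$name[i]]]
    if (beta != 0)
      v <- v + beta^2 * truncNormMoments(cv$mean[i], cv$sd[i],
                                         cv$min[i], cv$max[i])$var
  }
  bsex <- params@effects[["sex"]]
  v + bsex^2 * params@sexPropMale * (1 - params@sexPropMale)
}

## Expectation of the linear predictor (without intercept).
.linearPredictorMean <- function(params) {
  cv <- params@covariates
  m <- 0
  for (i in seq_len(nrow(cv))) {
    beta <- params@effects[[cv$name[i]]]
    if (beta != 0)
      m <- m + beta * truncNormMoments(cv$mean[i], cv$sd[i],
                                       cv$min[i], cv$max[i])$mean
  }
  m + params@effects[["sex"]] * params@sexPropMale
}

#' Residual SD of the grayscale model implied by the variance budget
#'
#' If `residualSD` was given explicitly it is returned as is; otherwise it
#' is solved from \eqn{\sigma_\epsilon^2 = } `totalGraySD`\eqn{^2 - }
#' Var(linear predictor), the latter computed analytically from the
#' truncated-normal covariate moments.
#'
#' @param params a [GenerativeParams-class].
#' @return residual SD in gray levels.
#' @export
residualGraySD <- function(params) {
  if (!is.na(params@residualSD)) return(params@residualSD)
  v <- params@totalGraySD^2 - .explainedVariance(params)
  if (v < 0)
    stop(sprintf(
      "variance budget violated: totalGraySD^2 = %.3f < explained variance %.3f",
      params@totalGraySD^2, .explainedVariance(params)))
  sqrt(v)
}

#' Intercept of the grayscale linear model
#'
#' Solved so the cohort expectation of the average grayscale value equals
#' `grayTarget` under the truncated-normal covariate expectations.
#'
#' @param params a [GenerativeParams-class].
#' @return intercept in gray levels.
#' @export
grayModelIntercept <- function(params) {
  params@grayTarget - .linearPredictorMean(params)
}

#' Construct generative parameters (normative-scenario defaults)
#'
#' Builds a [GenerativeParams-class] whose defaults describe a normative
#' scenario: covariate truncated-normal moments of a 397-eye adult
#' cohort (age 44.63 +/- 16.43 y on 18-80, axial length 23.73 +/- 1.13 mm,
#' image quality 55.4 +/- 4.35 on 45-65, ...), non-zero grayscale slopes
#' for age (-0.053), axial length (-0.664), RPE grayscale (0.372) and
#' image quality (0.658), sector grayscale offsets and thickness means of
#' the cohort Total row, a target average grayscale of 164.82 with cohort
#' SD 5.69, and unit-mean gamma speckle of shape 40. RPE grayscale moments
#' (170 +/- 8) are a package default; no normative table reports them.
#'
#' @param covariates optional replacement covariate table
#'   (`name, mean, sd, min, max`).
#' @param sexPropMale proportion of males.
#' @param effects named slopes (gray levels per covariate unit); names must
#'   match the covariate names plus `sex`.
#' @param grayTarget cohort mean of the average grayscale value.
#' @param totalGraySD target cohort SD of the average grayscale value.
#' @param residualSD residual SD override; `NA` (default) solves it from
#'   the variance budget.
#' @param sectorGrayOffsets named sector offsets (gray levels) relative to
#'   the eye average, order `T, IT, IN, N, SN, ST`.
#' @param sectorThickness named mean sector thicknesses in micrometers.
#' @param thickSD between-eye SD of the common thickness deviation (um).
#' @param speckleShape gamma speckle shape (`Inf` = no speckle).
#' @param seed master seed.
#' @return a validated [GenerativeParams-class].
#' @examples
#' p <- generativeParams(seed = 1)
#' cohort <- sampleCohort(p, 5)
#' cohort$true_avg_gray
#' @export
generativeParams <- function(covariates = NULL,
                             sexPropMale = 0.494,
                             effects = c(age = -0.053, sex = 0, se = 0,
                                         bcva = 0, al = -0.664, iop = 0,
                                         vf_md = 0, rpe_gray = 0.372,
                                         imageq = 0.658),
                             grayTarget = 164.82,
                             totalGraySD = 5.69,
                             residualSD = NA_real_,
                             sectorGrayOffsets = c(T = 0.38, IT = 0.79,
                                                   IN = 0.95, N = -1.56,
                                                   SN = 0.27, ST = 0.27),
                             sectorThickness = c(T = 84.77, IT = 144.34,
                                                 IN = 123.74, N = 79.59,
                                                 SN = 124.30, ST = 132.32),
                             thickSD = 8.89,
                             speckleShape = 40,
                             seed = 20201) {
  if (is.null(covariates))
    covariates <- data.frame(
      name = c("age", "se", "bcva", "al", "iop", "vf_md", "rpe_gray", "imageq"),
      mean = c(44.63, -0.78, 0.006, 23.73, 14.43, -1.01, 170, 55.4),
      sd   = c(16.43, 1.85, 0.075, 1.13, 2.87, 1.37, 8, 4.35),
      min  = c(18, -6, -0.2, 20.7, 7.9, -2.47, 140, 45),
      max  = c(80, 3.5, 0.3, 26.0, 21, 2.75, 200, 65),
      stringsAsFactors = FALSE
    )
  missing_eff <- setdiff(c(covariates$name, "sex"), names(effects))
  if (length(missing_eff))
    effects[missing_eff] <- 0
  new("GenerativeParams",
      covariates = covariates, sexPropMale = sexPropMale,
      effects = effects, grayTarget = grayTarget,
      totalGraySD = totalGraySD, residualSD = residualSD,
      sectorGrayOffsets = sectorGrayOffsets,
      sectorThickness = sectorThickness, thickSD = thickSD,
      speckleShape = speckleShape, seed = seed)
}

## Inverse-CDF draw from a truncated normal (deterministic given the RNG
## stream; exact, no rejection).
.rtruncnorm <- function(n, mean, sd, min, max) {
  if (sd == 0) return(rep(mean, n))
  pa <- pnorm(min, mean, sd)
  pb <- pnorm(max, mean, sd)
  qnorm(runif(n, pa, pb), mean, sd)
}

#' Derive a per-eye seed from the master seed
#'
#' Splitting rule used by the renderer and the pipeline so that each eye's
#' image is reproducible in isolation: a fixed multiplicative hash of the
#' master seed plus a subject-id offset, reduced modulo \eqn{2^{31}-1}.
#'
#' @param master master seed (integer).
#' @param subjectId subject identifier (integer).
#' @return an integer seed in \[1, 2^31 - 1\].
#' @export
deriveEyeSeed <- function(master, subjectId) {
  s <- ((master %% 2147483647) * 48271 + subjectId * 10007) %% 2147483647
  as.integer(ifelse(s == 0, 1, s))
}

## Column-count weights of the six sectors (T and N span 90 deg, rest 45).
.sectorWeights <- function() {
  setNames(c(0.25, 0.125, 0.125, 0.25, 0.125, 0.125), .SECTORS)
}

#' Sample a synthetic cohort
#'
#' Draws `n` subjects: covariates independently from truncated normal
#' distributions with the configured moments (sex Bernoulli), then the true
#' average grayscale value from the linear determinant model
#' `intercept + sum(slope_j * covariate_j) + eps`, with
#' `eps ~ N(0, residualGraySD(params))`. Sector grayscale truths are the
#' average plus the configured sector offsets; sector thickness truths are
#' the configured sector means plus a common per-eye deviation
#' (`N(0, thickSD)`, truncated at +/- 3 SD). Deterministic given
#' `params@seed`.
#'
#' @param params a [GenerativeParams-class].
#' @param n number of subjects (>= 0).
#' @return data.frame with one row per eye: `subject_id`, the covariates
#'   (`age, sex, se, bcva, al, iop, vf_md, rpe_gray, imageq`), `laterality`
#'   and truth columns prefixed `true_`.
#' @export
sampleCohort <- function(params, n) {
  validObject(params)
  if (length(n) != 1 || is.na(n) || n < 0)
    stop("n must be a single non-negative integer")
  n <- as.integer(n)
  sigma <- residualGraySD(params)  # fails early on a bad variance budget
  intercept <- grayModelIntercept(params)

  set.seed(as.integer(params@seed))
  cv <- params@covariates
  out <- data.frame(subject_id = seq_len(n))
  for (i in seq_len(nrow(cv)))
    out[[cv$name[i]]] <- .rtruncnorm(n, cv$mean[i], cv$sd[i], cv$min[i], cv$max[i])
  out$sex <- as.integer(runif(n) < params@sexPropMale)
  out$laterality <- ifelse(runif(n) < 0.5, "OD", "OS")

  lp <- rep(intercept, n)
  for (i in seq_len(nrow(cv))) {
    beta <- params@effects[[cv$name[i]]]
    if (beta != 0) lp <- lp + beta * out[[cv$name[i]]]
  }
  lp <- lp + params@effects[["sex"]] * out$sex
  eps <- if (sigma > 0) rnorm(n, 0, sigma) else numeric(n)
  avg <- pmin(pmax(lp + eps, 0), 255)
  out$true_avg_gray <- avg
  for (s in .SECTORS)
    out[[paste0("true_gray_", s)]] <-
      pmin(pmax(avg + params@sectorGrayOffsets[[s]], 0), 255)

  delta <- if (params@thickSD > 0)
    .rtruncnorm(n, 0, params@thickSD, -3 * params@thickSD, 3 * params@thickSD)
  else numeric(n)
  w <- .sectorWeights()
  for (s in .SECTORS)
    out[[paste0("true_thick_", s)]] <- params@sectorThickness[[s]] + delta
  out$true_thick_mean <- as.numeric(
    as.matrix(out[paste0("true_thick_", .SECTORS)]) %*% w[.SECTORS])

  # column order per the documented CSV schema
  lead <- c("subject_id", cv$name[cv$name %in% c("age")], "sex",
            setdiff(cv$name, c("age", "rpe_gray", "imageq")),
            "rpe_gray", "imageq", "laterality")
  lead <- unique(lead)
  out[, c(lead, setdiff(names(out), lead))]
}

## Smooth double-hump thickness profile (um) over the column angles, whose
## per-sector means equal the requested sector thicknesses exactly.
## Construction: a raised double von-Mises-shaped base (bumps at the
## superior and inferior poles) times a smooth per-sector gain interpolated
## periodically between sector centers; gains are fitted by multiplicative
## fixed-point iteration.
.thicknessProfile <- function(anglesDeg, sectorThickness, kappa = 2, amp = 0.9) {
  th <- anglesDeg * pi / 180
  base <- 1 + amp * (exp(kappa * (cos(th - pi / 2) - 1)) +
                     exp(kappa * (cos(th - 3 * pi / 2) - 1)))
  scheme <- sectorScheme()
  sec <- sectorOfAngle(anglesDeg, scheme)
  centers <- setNames(c(0, 292.5, 247.5, 180, 112.5, 67.5), .SECTORS)
  ord <- order(centers)
  cx <- centers[ord]
  gains <- setNames(rep(1, 6), .SECTORS)
  interp <- function(g) {
    gy <- g[names(cx)]
    x <- c(cx[length(cx)] - 360, cx, cx[1] + 360)
    y <- c(gy[length(gy)], gy, gy[1])
    stats::approx(x, y, xout = anglesDeg, method = "linear")$y
  }
  for (it in 1:400) {
    t <- interp(gains) * base
    m <- vapply(.SECTORS, function(s) mean(t[sec == s]), numeric(1))
    ratio <- sectorThickness[.SECTORS] / m
    gains <- gains * ratio
    if (max(abs(ratio - 1)) < 1e-13) break
  }
  t <- interp(gains) * base
  m <- vapply(.SECTORS, function(s) mean(t[sec == s]), numeric(1))
  if (max(abs(m - sectorThickness[.SECTORS])) > 1e-6)
    stop("thickness profile fitting did not converge to the sector means")
  t
}

#' Render one synthetic circular B-scan
#'
#' Renders a subject's eye as a 1024-column circular-scan B-scan: a smooth
#' internal limiting membrane, a pRNFL band whose per-column thickness
#' follows a smooth double-hump profile with sector means exactly equal to
#' the subject's thickness truths, a composite inner-retina band, and an
#' RPE band. pRNFL reflectivity is constant within each sector at the
#' subject's sector grayscale truth; pixel intensities are layer
#' reflectivity times unit-mean gamma speckle, clipped and quantized to
#' 8 bits. Left eyes (`laterality == "OS"`) are rendered in the mirrored
#' angular frame (see [columnAngle()]).
#'
#' @param truth one cohort row (as returned by [sampleCohort()]), or any
#'   list with the same fields.
#' @param params the [GenerativeParams-class] used for the cohort.
#' @param height image height in pixels.
#' @param axialScale axial sampling in micrometers per pixel.
#' @param nCols number of A-scan columns.
#' @param seed RNG seed for the speckle; defaults to
#'   `deriveEyeSeed(params@seed, truth$subject_id)`.
#' @return list with elements `image` ([BScanImage-class]) and `truth`
#'   ([GroundTruth-class]).
#' @export
renderBScan <- function(truth, params, height = 480, axialScale = 5,
                        nCols = 1024,
                        seed = deriveEyeSeed(params@seed, truth$subject_id)) {
  W <- as.integer(nCols); H <- as.integer(height)
  lat <- as.character(truth$laterality)
  ang <- columnAngle(seq_len(W), W, lat)

  sectorThick <- setNames(
    vapply(.SECTORS, function(s) truth[[paste0("true_thick_", s)]], numeric(1)),
    .SECTORS)
  sectorGray <- setNames(
    vapply(.SECTORS, function(s) truth[[paste0("true_gray_", s)]], numeric(1)),
    .SECTORS)

  tProf <- .thicknessProfile(ang, sectorThick)                  # um
  ilm <- 140 + 8 * sin(ang * pi / 180)                          # rows
  rnflPost <- ilm + tProf / axialScale
  rpeInner <- ilm + 280 / axialScale
  rpeOuter <- rpeInner + 40 / axialScale
  if (max(rpeOuter) >= H - 1)
    stop(sprintf("layers exceed image height: need at least %d rows",
                 ceiling(max(rpeOuter)) + 2))
  if (any(rnflPost > rpeInner + 1e-9))
    stop("pRNFL thickness exceeds the inner retina depth at this axial scale")

  sec <- sectorOfAngle(ang, sectorScheme())
  rnflRefl <- unname(sectorGray[sec])
  rpeRefl <- rep(as.numeric(truth$rpe_gray), W)

  reflVitreous <- 25; reflInner <- 110; reflBelow <- 55
  img <- matrix(reflVitreous, H, W)
  u1 <- ceiling(ilm); u2 <- ceiling(rnflPost)
  u3 <- ceiling(rpeInner); u4 <- ceiling(rpeOuter)
  for (c in seq_len(W)) {
    if (u2[c] > u1[c]) img[u1[c]:(u2[c] - 1), c] <- rnflRefl[c]
    if (u3[c] > u2[c]) img[u2[c]:(u3[c] - 1), c] <- reflInner
    if (u4[c] > u3[c]) img[u3[c]:(u4[c] - 1), c] <- rpeRefl[c]
    img[u4[c]:H, c] <- reflBelow
  }

  if (is.finite(params@speckleShape)) {
    set.seed(as.integer(seed))
    sh <- params@speckleShape
    img <- img * matrix(rgamma(H * W, shape = sh, rate = sh), H, W)
  }
  img <- round(pmin(pmax(img, 0), 255))

  image <- new("BScanImage", pixels = img, axialScale = axialScale,
               scanDiameter = 3.46, laterality = lat,
               qualityFactor = NA_real_)
  gt <- new("GroundTruth", ilm = ilm, rnflPost = rnflPost,
            rpeInner = rpeInner, rpeOuter = rpeOuter,
            rnflRefl = rnflRefl, rpeRefl = rpeRefl)
  list(image = image, truth = gt)
}

#' Degrade a B-scan to a target image quality
#'
#' Adds zero-mean Gaussian noise whose SD decreases linearly in the quality
#' knob, calibrated so that [computeImageQ()] recovers the knob to within
#' about 2 units on rendered scans. At the calibration maximum the image is
#' returned unchanged (bit-identical). The noise is deliberately
#' mean-preserving inside tissue so that layer grayscale truths remain well
#' defined; the quality-grayscale association of the cohort lives in the
#' generative linear model, not in the degradation.
#'
#' @param image a [BScanImage-class].
#' @param imageq target quality, inside `calRange`.
#' @param calRange calibration range of the quality knob.
#' @param sigmaMax noise SD (gray levels) at the calibration minimum.
#' @return a degraded [BScanImage-class] carrying `imageq` in its
#'   `qualityFactor` slot (or the input, untouched, at the calibration max).
#' @export
degradeQuality <- function(image, imageq, calRange = c(40, 70),
                           sigmaMax = 24) {
  stopifnot(is(image, "BScanImage"))
  if (length(imageq) != 1 || !is.finite(imageq) ||
      imageq < calRange[1] || imageq > calRange[2])
    stop(sprintf("imageq must lie in the calibration range [%g, %g]",
                 calRange[1], calRange[2]))
  sigma <- sigmaMax * (calRange[2] - imageq) / (calRange[2] - calRange[1])
  if (sigma == 0) return(image)
  p <- image@pixels
  p <- round(pmin(pmax(p + matrix(rnorm(length(p), 0, sigma),
                                  nrow(p), ncol(p)), 0), 255))
  new("BScanImage", pixels = p, axialScale = image@axialScale,
      scanDiameter = image@scanDiameter, laterality = image@laterality,
      qualityFactor = imageq)
}
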