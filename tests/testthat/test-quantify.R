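SECT <- c("T", "IT", "IN", "N", "SN", "ST")

test_that("columnAngle anchors and the OS mirror formula", {
  expect_equal(columnAngle(1, 1024, "OD"), 0)
  expect_equal(columnAngle(513, 1024, "OD"), 180)
  expect_equal(columnAngle(257, 1024, "OS"), 270)
  # brute force over all columns: OS is the mirror of OD
  od <- columnAngle(1:1024, 1024, "OD")
  os <- columnAngle(1:1024, 1024, "OS")
  expect_equal(os, (360 - od) %% 360)
  expect_true(all(od >= 0 & od < 360))
  expect_error(columnAngle(0, 1024), "indices")
  expect_error(columnAngle(1025, 1024), "indices")
})

test_that("sectorOfAngle follows the half-open sector scheme", {
  expect_equal(sectorOfAngle(180), "N")
  expect_equal(sectorOfAngle(0), "T")
  expect_equal(sectorOfAngle(100), "SN")
  expect_equal(sectorOfAngle(45), "ST")
  expect_equal(sectorOfAngle(315), "T")
  expect_equal(sectorOfAngle(c(44.999, 135, 224.999, 225, 270, 314.999)),
               c("T", "N", "N", "IN", "IT", "IT"))
  expect_error(sectorOfAngle(-1), "0, 360")
  expect_error(sectorOfAngle(360), "0, 360")
  # the scheme partitions [0, 360): every angle gets exactly one label
  a <- seq(0, 359.9, by = 0.1)
  expect_false(anyNA(sectorOfAngle(a)))
})

test_that("layerGrayscale/layerThickness equal a brute-force loop on a toy image", {
  set.seed(5)
  p <- matrix(round(runif(8 * 64) * 255), 8, 64)
  img <- new("BScanImage", pixels = p, axialScale = 5, laterality = "OD")
  upper <- runif(64, 1, 3)
  lower <- upper + runif(64, 0, 4)
  cols <- c(2, 3, 7, 11, 16, 40, 64)
  tot <- 0; np <- 0; thick <- 0
  for (c in cols) {
    a <- ceiling(upper[c]); b <- ceiling(lower[c])
    r <- a
    while (r < b) { tot <- tot + p[r, c]; np <- np + 1; r <- r + 1 }
    thick <- thick + (lower[c] - upper[c]) * 5
  }
  expect_equal(layerGrayscale(img, upper, lower, cols), tot / np,
               tolerance = 1e-12)
  expect_equal(layerThickness(upper, lower, 5, cols), thick / length(cols),
               tolerance = 1e-12)
})

test_that("layerGrayscale: constants, pixel weighting, degenerate bands", {
  img <- new("BScanImage", pixels = matrix(100, 10, 64), laterality = "OD")
  expect_equal(layerGrayscale(img, rep(2, 64), rep(8, 64)), 100)
  # two columns, equal band height, values 100 and 200 -> 150
  p2 <- matrix(100, 10, 64); p2[, 2] <- 200
  img2 <- new("BScanImage", pixels = p2, laterality = "OD")
  expect_equal(layerGrayscale(img2, rep(2, 64), rep(6, 64), columns = 1:2), 150)
  # unequal heights weight by pixels, not columns
  expect_equal(layerGrayscale(img2, rep(2, 64), c(8, rep(4, 63)), columns = 1:2),
               (100 * 6 + 200 * 2) / 8)
  expect_error(layerGrayscale(img, rep(2, 64), rep(2, 64)),
               class = "prnflEmptyBand")
  expect_error(layerGrayscale(img, rep(8, 64), rep(2, 64)), "upper")
  expect_equal(layerThickness(rep(2, 64), rep(2, 64), 5), 0)
  expect_equal(layerThickness(rep(2, 64), rep(22, 64), 5), 100)
  expect_error(layerThickness(rep(8, 64), rep(2, 64), 5), "ordering")
})

test_that("measurement closure: sector decomposition reproduces the means", {
  eye <- phantomEye()
  gt <- eye$truth
  b <- new("LayerBoundaries", ilm = gt@ilm, rnflPost = gt@rnflPost,
           rpeInner = gt@rpeInner, rpeOuter = gt@rpeOuter)
  m <- measureEye(eye$image, b)
  W <- 1024
  sec <- sectorOfAngle(columnAngle(1:W, W, laterality(eye$image)))
  npix <- vapply(SECT, function(s) {
    cols <- which(sec == s)
    sum(pmax(ceiling(gt@rnflPost[cols]) - ceiling(gt@ilm[cols]), 0))
  }, numeric(1))
  ncols <- vapply(SECT, function(s) sum(sec == s), numeric(1))
  expect_equal(sum(m@graySector * npix) / sum(npix), m@grayMean,
               tolerance = 1e-9)
  expect_equal(sum(m@thickSector * ncols) / sum(ncols), m@thickMean,
               tolerance = 1e-9)
  # range preservation
  expect_gte(min(m@graySector), 0); expect_lte(max(m@graySector), 255)
})

test_that("laterality invariance: OS eye equals its mirrored OD rendering", {
  p <- generativeParams(seed = 77)
  co <- sampleCohort(p, 4)
  i <- which(co$laterality == "OS")[1]
  expect_false(is.na(i))
  eye <- renderBScan(co[i, ], p)
  gt <- eye$truth
  b <- new("LayerBoundaries", ilm = gt@ilm, rnflPost = gt@rnflPost,
           rpeInner = gt@rpeInner, rpeOuter = gt@rpeOuter)
  mOS <- measureEye(eye$image, b)
  # angle-preserving column mirror: column 1 fixed, the rest reversed
  W <- 1024
  perm <- c(1, W:2)
  imgOD <- new("BScanImage", pixels = pixels(eye$image)[, perm],
               axialScale = axialScale(eye$image), laterality = "OD")
  bOD <- new("LayerBoundaries", ilm = gt@ilm[perm], rnflPost = gt@rnflPost[perm],
             rpeInner = gt@rpeInner[perm], rpeOuter = gt@rpeOuter[perm])
  mOD <- measureEye(imgOD, bOD)
  expect_equal(mOS@graySector, mOD@graySector, tolerance = 1e-12)
  expect_equal(mOS@thickSector, mOD@thickSector, tolerance = 1e-12)
  expect_equal(mOS@grayMean, mOD@grayMean, tolerance = 1e-12)
})

test_that("equal sector truths give equal sector grays; lowered nasal is lowest", {
  # symmetric phantom: identical reflectivity and thickness in all sectors
  p <- generativeParams(seed = 3, speckleShape = Inf)
  row <- sampleCohort(p, 1)[1, ]
  for (s in SECT) {
    row[[paste0("true_gray_", s)]] <- 160
    row[[paste0("true_thick_", s)]] <- 110
  }
  eye <- renderBScan(row, p)
  gt <- eye$truth
  b <- new("LayerBoundaries", ilm = gt@ilm, rnflPost = gt@rnflPost,
           rpeInner = gt@rpeInner, rpeOuter = gt@rpeOuter)
  m <- measureEye(eye$image, b)
  expect_equal(unname(m@graySector), rep(m@grayMean, 6), tolerance = 1e-9)

  # nasal reflectivity lowered -> nasal sector strictly lowest
  row$true_gray_N <- 158
  eye2 <- renderBScan(row, p)
  gt2 <- eye2$truth
  b2 <- new("LayerBoundaries", ilm = gt2@ilm, rnflPost = gt2@rnflPost,
            rpeInner = gt2@rpeInner, rpeOuter = gt2@rpeOuter)
  m2 <- measureEye(eye2$image, b2)
  expect_equal(names(which.min(m2@graySector)), "N")
})

test_that("computeImageQ anchors: clean scans high, pure noise unusable", {
  eye <- noiselessEye()
  expect_gte(computeImageQ(eye$image), 65)
  set.seed(13)
  noise <- new("BScanImage",
               pixels = matrix(round(runif(480 * 256) * 255), 480, 256),
               laterality = "OD")
  expect_lt(computeImageQ(noise), 45)
})

test_that("computeImageQ recovers the degradation knob, monotonically", {
  eye <- phantomEye()
  qs <- c(45, 50, 55, 60, 65)
  rec <- matrix(NA_real_, 5, length(qs))
  for (s in 1:5) for (j in seq_along(qs)) {
    set.seed(600 + 10 * s + j)
    rec[s, j] <- computeImageQ(degradeQuality(eye$image, qs[j]))
  }
  avg <- colMeans(rec)
  expect_true(all(abs(avg - qs) <= 2))
  expect_equal(cor(qs, avg, method = "spearman"), 1)
})

test_that("measureEye refuses QC-failed input unless overridden", {
  eye <- phantomEye()
  den <- denoiseBScan(eye$image, 3)
  b <- segmentBoundaries(den)
  thin <- new("LayerBoundaries", ilm = b@ilm, rnflPost = b@ilm + 1,
              rpeInner = b@rpeInner, rpeOuter = b@rpeOuter)
  expect_error(measureEye(den, thin), class = "prnflQCRefusal")
  m <- measureEye(den, thin, overrideQC = TRUE)
  expect_s4_class(m, "PRNFLMeasurement")
})

test_that("measurementRow emits the documented columns in order", {
  eye <- phantomEye()
  den <- denoiseBScan(eye$image, 3)
  m <- measureEye(den, segmentBoundaries(den), imageq = 55)
  row <- measurementRow(m)
  expect_identical(names(row),
    c("gray_mean", "gray_T", "gray_IT", "gray_IN", "gray_N", "gray_SN",
      "gray_ST", "thick_mean", "thick_T", "thick_IT", "thick_IN", "thick_N",
      "thick_SN", "thick_ST", "rpe_gray", "imageq", "qc_pass"))
  expect_true(row$qc_pass)
  expect_equal(row$imageq, 55)
})
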