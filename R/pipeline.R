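## End-to-end pipeline: synthesize -> (degrade) -> denoise -> segment ->
## QC -> measure -> merge -> statistics, with exclusion accounting that
## mirrors a clinical reading workflow (quality gate, boundary
## misidentification, manual motion-artifact flags).

#' Build a pipeline configuration
#'
#' All scenario-level defaults (quality gate 45, age bins, alpha 0.05,
#' Bonferroni family of 15 sector pairs, forced axial length) live here
#' rather than in code paths.
#'
#' @param params a [GenerativeParams-class] (the synthetic cohort
#'   scenario); ignored when a pre-built cohort is passed to
#'   [runPipeline()].
#' @param n number of eyes to synthesize.
#' @param outDir output directory for CSV/JSON artifacts (`NULL` = keep
#'   results in memory only).
#' @param writeImages also write per-eye PNG + ground-truth JSON sidecars
#'   under `outDir/images` (slow; off by default).
#' @param kernel median pre-filter kernel for segmentation.
#' @param maxJump,lambda segmentation smoothness settings
#'   (see [segmentBoundaries()]).
#' @param qcThicknessBand,qcMaxRoughness QC rule settings
#'   (see [flagMisidentification()]).
#' @param qualityGate minimum usable image quality; eyes at or below the
#'   gate are excluded (clinical practice treats quality factors of 45
#'   and below as unusable).
#' @param alpha univariable carry-forward significance level.
#' @param forced covariates forced into the multivariable model.
#' @param ageBins age-group edges for the normative table.
#' @param height,axialScale rendering geometry.
#' @return a `prnflConfig` list.
#' @export
pipelineConfig <- function(params = generativeParams(), n = 397,
                           outDir = NULL, writeImages = FALSE,
                           kernel = 3, maxJump = 3, lambda = 20,
                           qcThicknessBand = c(30, 250), qcMaxRoughness = 2,
                           qualityGate = 45, alpha = 0.05, forced = "al",
                           ageBins = .DEFAULT_AGE_BINS,
                           height = 480, axialScale = 5) {
  structure(list(params = params, n = n, outDir = outDir,
                 writeImages = writeImages, kernel = kernel,
                 maxJump = maxJump, lambda = lambda,
                 qcThicknessBand = qcThicknessBand,
                 qcMaxRoughness = qcMaxRoughness,
                 qualityGate = qualityGate, alpha = alpha, forced = forced,
                 ageBins = ageBins, height = height,
                 axialScale = axialScale),
            class = "prnflConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Any field of [pipelineConfig()] may appear in the file; generator
#' parameters may be overridden under a `params:` block whose entries are
#' passed to [generativeParams()].
#'
#' @param path YAML file.
#' @return a `prnflConfig` list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 treats a bare `n` key as boolean FALSE; map it back to the
  # field name so `n: 397` works as documented
  names(y)[names(y) == "FALSE"] <- "n"
  paramArgs <- y$params
  y$params <- NULL
  params <- if (is.null(paramArgs)) generativeParams()
            else do.call(generativeParams, paramArgs)
  do.call(pipelineConfig, c(list(params = params), y))
}

#' Process one eye through the imaging stages
#'
#' Render (or take a supplied image), degrade to the eye's quality value,
#' median-filter, segment, QC, measure. Used by [runPipeline()] and
#' available directly for single-eye work.
#'
#' @param truth one cohort row.
#' @param config a `prnflConfig`.
#' @return list with `image`, `groundTruth`, `boundaries`, `qc`,
#'   `measurement` (the last three `NULL` if the eye was gated out).
#' @export
processEye <- function(truth, config) {
  params <- config$params
  rb <- renderBScan(truth, params, height = config$height,
                    axialScale = config$axialScale)
  eyeSeed <- deriveEyeSeed(params@seed, truth$subject_id)
  set.seed((eyeSeed %% 2147483000L) + 1L)
  img <- degradeQuality(rb$image, truth$imageq)
  den <- denoiseBScan(img, config$kernel)
  bounds <- segmentBoundaries(den, maxJump = config$maxJump,
                              lambda = config$lambda)
  qc <- flagMisidentification(den, bounds,
                              thicknessBand = config$qcThicknessBand,
                              maxRoughness = config$qcMaxRoughness)
  meas <- if (isMisidentified(qc)) NULL else
    measureEye(img, bounds, imageq = truth$imageq, qc = qc)
  list(image = img, groundTruth = rb$truth, boundaries = bounds, qc = qc,
       measurement = meas)
}

#' Run the full pipeline
#'
#' Executes synthesize -> degrade -> segment -> measure -> analyze. Eyes
#' failing the quality gate, flagged by segmentation QC, or carrying a
#' manual `motion_artifact` flag are excluded and counted by reason; the
#' manifest asserts that recruited = analyzed + sum(excluded). Reruns with
#' the same configuration and seed are bit-identical.
#'
#' @param config a `prnflConfig` from [pipelineConfig()].
#' @param cohort optional pre-built cohort data.frame (as from
#'   [sampleCohort()] or [readCohort()]); `NULL` samples `config$n` eyes
#'   from `config$params`.
#' @return list with `manifest`, the merged `cohort` (covariates +
#'   measurement columns + `excluded`), and `summaries` (age-group table,
#'   sector comparisons, univariable screen, multivariable fit).
#' @export
runPipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "prnflConfig"))
  if (is.null(cohort)) cohort <- sampleCohort(config$params, config$n)
  n <- nrow(cohort)

  if (!is.null(config$outDir))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  imgDir <- if (!is.null(config$outDir) && config$writeImages)
    file.path(config$outDir, "images") else NULL
  if (!is.null(imgDir)) dir.create(imgDir, showWarnings = FALSE)

  excluded <- rep(NA_character_, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    truth <- cohort[i, ]
    id <- truth$subject_id
    if (!is.null(cohort$motion_artifact) &&
        isTRUE(as.logical(truth$motion_artifact))) {
      excluded[i] <- "motion_artifact"
      next
    }
    if (truth$imageq <= config$qualityGate) {
      excluded[i] <- "quality_gate"
      next
    }
    eye <- tryCatch(processEye(truth, config), error = function(e)
      stop(sprintf("pipeline stage failed for eye %s: %s", id,
                   conditionMessage(e)), call. = FALSE))
    if (!is.null(imgDir)) {
      writeBScan(eye$image, file.path(imgDir, sprintf("eye_%04d.png", id)))
      writeGroundTruth(eye$groundTruth,
                       file.path(imgDir, sprintf("eye_%04d_truth.json", id)))
    }
    if (isMisidentified(eye$qc)) {
      excluded[i] <- "boundary_misidentification"
      next
    }
    rows[[i]] <- measurementRow(eye$measurement)
  }

  keep <- !vapply(rows, is.null, logical(1))
  if (any(keep)) {
    template <- rows[keep][[1]]
    blank <- template[1, ]; blank[1, ] <- NA
    meas <- do.call(rbind,
                    lapply(rows, function(r) if (is.null(r)) blank else r))
    merged <- cbind(cohort, meas)
  } else {
    merged <- cohort
  }
  merged$excluded <- excluded

  reasons <- c("quality_gate", "boundary_misidentification", "motion_artifact")
  excl <- setNames(vapply(reasons, function(r) sum(excluded == r, na.rm = TRUE),
                          numeric(1)), reasons)
  nAnalyzed <- sum(is.na(excluded))
  stopifnot(n == nAnalyzed + sum(excl))  # accounting conservation
  manifest <- list(n_recruited = n, n_analyzed = nAnalyzed,
                   exclusions = as.list(excl),
                   seed = as.integer(config$params@seed))

  analyzed <- analyzedSubset(merged)
  summaries <- if (nAnalyzed >= 3) {
    uni <- univariableScreen(analyzed, alpha = config$alpha)
    carry <- uni$covariate[uni$carry_forward %in% TRUE]
    list(
      ageGroups = ageGroupSummary(analyzed, bins = config$ageBins),
      sectorComparisons = compareSectors(analyzed),
      univariable = uni,
      multivariable = multivariableFit(analyzed, carryForward = carry,
                                       forced = config$forced)
    )
  } else NULL

  if (!is.null(config$outDir)) {
    writeCohort(merged, file.path(config$outDir, "cohort.csv"))
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(config$outDir) && !is.null(summaries)) {
    write.csv(summaries$ageGroups,
              file.path(config$outDir, "age_group_summary.csv"),
              row.names = FALSE)
    sc <- summaries$sectorComparisons
    write.csv(sc, file.path(config$outDir, "sector_comparisons.csv"),
              row.names = FALSE)
    write.csv(summaries$univariable,
              file.path(config$outDir, "univariable.csv"), row.names = FALSE)
    mv <- summaries$multivariable
    write.csv(mv, file.path(config$outDir, "multivariable.csv"),
              row.names = FALSE)
  }
  list(manifest = manifest, cohort = merged, summaries = summaries)
}
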