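## Shared memoised fixtures so expensive artifacts (full-cohort pipeline
## runs, rendered phantoms) are built once per test session.

.sharedCache <- new.env(parent = emptyenv())

memoised <- function(key, expr) {
  if (!exists(key, envir = .sharedCache))
    assign(key, force(expr), envir = .sharedCache)
  get(key, envir = .sharedCache)
}

## Full 397-eye pipeline run under the default generative parameters
## (used by the end-to-end acceptance blocks).
acceptancePipeline <- function() {
  memoised("acceptance397", {
    runPipeline(pipelineConfig(n = 397))
  })
}

## One rendered speckled eye under study defaults.
phantomEye <- function() {
  memoised("phantom1", {
    p <- generativeParams(seed = 501)
    co <- sampleCohort(p, 1)
    c(renderBScan(co[1, ], p), list(row = co[1, ], params = p))
  })
}

## One noise-free (speckle-less) rendered eye.
noiselessEye <- function() {
  memoised("noiseless1", {
    p <- generativeParams(seed = 502, speckleShape = Inf)
    co <- sampleCohort(p, 1)
    c(renderBScan(co[1, ], p), list(row = co[1, ], params = p))
  })
}
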