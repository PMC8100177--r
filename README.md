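# pRNFLgray

Sectoral grayscale and thickness quantification of the peripapillary
retinal nerve fiber layer (pRNFL) on circular OCT B-scans.

## What this is

The brightness (grayscale value, 0–255) of the pRNFL on spectral-domain
OCT reflects axonal integrity and falls before thickness does in early
glaucoma, which makes normative grayscale values clinically interesting.
Estimating them requires a full chain: segment the internal limiting
membrane (ILM), the posterior pRNFL boundary and the retinal pigment
epithelium (RPE) band on a circular peripapillary scan; average intensity
and thickness over six angular sectors (temporal, superior-temporal,
superior-nasal, nasal, inferior-nasal, inferior-temporal); gate out
low-quality scans and misidentified boundaries; then summarize the cohort
(age-group tables, sector comparisons, determinant regressions).

`pRNFLgray` implements that chain in Bioconductor-style S4, plus a
synthetic B-scan and cohort generator with exact ground truth, so the
entire pipeline is testable end to end without any patient data:

* **synthesis** — `generativeParams()`, `sampleCohort()`,
  `renderBScan()`, `degradeQuality()`: truncated-normal covariates, a
  linear determinant model for the average grayscale value, double-hump
  thickness anatomy, unit-mean gamma speckle, quality-dependent noise;
* **segmentation** — `denoiseBScan()`, `segmentBoundaries()`,
  `flagMisidentification()`: sequential dynamic-programming paths
  (gradient costs for ILM/RPE, a two-segment changepoint cost for the
  posterior pRNFL boundary), sub-pixel refinement, deterministic QC;
* **quantification** — `measureEye()`, `layerGrayscale()`,
  `layerThickness()`, `computeImageQ()`: six half-open sectors, pixel-
  weighted grayscale with exact closure, calibrated image-quality proxy;
* **statistics** — `ageGroupSummary()`, `compareSectors()`,
  `univariableScreen()`, `multivariableFit()`, `iccTwoObservers()`;
* **pipeline & I/O** — `pipelineConfig()`, `runPipeline()`, PNG/TIFF,
  CSV and JSON round trips, a CLI at `inst/cli/prnflpipe.R`.

## Worked example

Sample a small cohort and render one eye:

```r
library(pRNFLgray)

params <- generativeParams(seed = 2024)   # normative-scenario defaults
cohort <- sampleCohort(params, n = 3)
cohort[, c("subject_id", "age", "al", "imageq", "laterality", "true_avg_gray")]
#>   subject_id      age       al   imageq laterality true_avg_gray
#> 1          1 60.46309 22.40015 50.24345         OS      157.6192
#> 2          2 38.36629 25.06997 57.35970         OD      160.3657
#> 3          3 52.61390 25.41508 59.71960         OD      162.9975

eye <- renderBScan(cohort[1, ], params)
eye$image
#> BScanImage: 480 x 1024 pixels (OS), 5 um/px axial, 3.46 mm circle
#>   intensity range [12, 255]
```

Degrade to the eye's quality value, segment, and measure:

```r
set.seed(deriveEyeSeed(params@seed, 1))
degraded <- degradeQuality(eye$image, cohort$imageq[1])
bounds <- segmentBoundaries(denoiseBScan(degraded, kernel = 3))
bounds
#> LayerBoundaries over 1024 columns
#>   ilm      rows 132.4-147.8 (median 139.9)
#>   rnflPost rows 148.5-173.5 (median 156.5)
#>   rpeInner rows 187.4-205.5 (median 196.4)
#>   rpeOuter rows 196.1-211.7 (median 203.6)

measureEye(degraded, bounds, imageq = cohort$imageq[1])
#> PRNFLMeasurement: gray 157.53 | thickness 92.27 um | RPE 160.71 | imageq 50.2
#>   sector gray:  T=158.00 IT=158.18 IN=158.16 N=155.09 SN=158.12 ST=157.86
#>   sector thickness: T=70.6 IT=129.1 IN=108.8 N=65.5 SN=110.2 ST=117.9
```

The recovered average grayscale value (157.53) matches this eye's
generative truth (157.62), and the nasal sector is, as expected, the
darkest.

Run the full pipeline on a cohort and inspect the summaries:

```r
cfg <- pipelineConfig(params = generativeParams(seed = 2024), n = 60)
res <- runPipeline(cfg)
str(res$manifest)
#> List of 4
#>  $ n_recruited: int 60
#>  $ n_analyzed : int 60
#>  $ exclusions :List of 3
#>   ..$ quality_gate              : num 0
#>   ..$ boundary_misidentification: num 0
#>   ..$ motion_artifact           : num 0
#>  $ seed       : int 2024

res$summaries$ageGroups[, c("age_group", "n", "gray_mean_mean",
                            "gray_mean_sd", "thick_mean_mean")]
#>   age_group  n gray_mean_mean gray_mean_sd thick_mean_mean
#> 1     18-29 11          167.0        7.382          108.62
#> 2     30-39  9          165.6        5.457          107.68
#> 3     40-49 12          165.2        6.473          105.75
#> 4     50-59 16          166.8        5.238          107.02
#> 5     60-69  9          165.0        3.361          105.45
#> 6      >=70  3          159.6        2.567           94.69
#> 7     Total 60          165.7        5.703          106.30

res$summaries$multivariable[, c("covariate", "included", "slope", "se", "p")]
#>     covariate included  slope     se        p
#> 1         age    FALSE     NA     NA       NA
#> ...
#> 5          al     TRUE -0.463 0.4864 3.45e-01
#> 9    rpe_gray     TRUE  0.363 0.0776 1.86e-05
#> 10     imageq     TRUE  0.690 0.1573 5.17e-05
```

Even at n = 60 the recovered multivariable slopes sit near their
generative values (RPE grayscale 0.372, image quality 0.658); the full
397-eye runs below pin them down within sampling error.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "prnflpipe.R", package="pRNFLgray"))')
Rscript $CLI synth   --n 10 --seed 7 --out data --images
Rscript $CLI segment --in data/images/eye_0001.png --out b.csv --qc qc.json
Rscript $CLI measure --img data/images/eye_0001.png --bounds b.csv --eye OD --out row.csv
Rscript $CLI run     --n 397 --seed 7 --out results
Rscript $CLI stats   --cohort results/cohort.csv --out tables
```

## Documentation

Every exported function carries full help (`?segmentBoundaries`, etc.);
the methods vignette (`vignettes/methods.Rmd`) documents the generative
model, the changepoint segmentation, the image-quality calibration, all
numerical conventions, and the package's limitations.
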