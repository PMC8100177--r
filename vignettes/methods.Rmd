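---
title: "Methods: synthetic pRNFL grayscale pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic pRNFL grayscale pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pRNFLgray)
```

# Scope

`pRNFLgray` quantifies the peripapillary retinal nerve fiber layer (pRNFL)
on circular spectral-domain OCT B-scans: grayscale value (0–255) and
thickness (µm), on average and in six angular sectors, together with the
normative statistics commonly reported for such measurements. Because no
patient scans ship with the package, a synthetic generator renders
B-scans with exact ground truth, so every downstream stage — segmentation,
quantification, statistics — is testable end to end.

This vignette documents the model, the algorithms, the calibrations, and
the numerical conventions. All defaults quoted here live in
`generativeParams()` and `pipelineConfig()`, not in code paths.

# The generative model

## Cohort

`sampleCohort()` draws `n` subjects. Each covariate (age, spherical
equivalent, BCVA, axial length, IOP, visual-field mean deviation, RPE
grayscale, image quality) is sampled independently from a truncated
normal distribution with configured mean, SD and bounds; sex is Bernoulli.
Sampling uses the inverse-CDF transform, so it is exact (no rejection) and
deterministic given the master seed.

The true average grayscale value of an eye follows a linear model:

$$\bar g = \beta_0 + \sum_j \beta_j x_j + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma_\varepsilon^2).$$

Default non-zero slopes: age −0.053, axial length −0.664, RPE grayscale
0.372, image quality 0.658 (gray levels per covariate unit). The intercept
is solved so the cohort expectation equals the configured target
(default 164.82), using the analytic truncated-normal means. The residual
SD is solved from a variance budget,
$\sigma_\varepsilon^2 = \mathrm{SD}_{\text{total}}^2 - \sum_j \beta_j^2
\mathrm{Var}(x_j)$, with the truncated-normal variances computed in closed
form (`truncNormMoments()`); a configuration whose slopes already explain
more than the target total SD (default 5.69) fails construction with an
error naming the budget. Sector grayscale truths are the eye average plus
constant sector offsets (nasal −1.56, inferior-nasal +0.95, …); sector
thickness truths are the configured sector means plus one common per-eye
deviation (`thickSD`, truncated at ±3 SD).

Covariates are independent by design: no correlation structure is
published for such cohorts, so univariable (marginal) coefficients are
*not* calibration targets — only the multivariable slopes are.

The RPE grayscale moments (170 ± 8 on [140, 200]) are a package default;
normative tables report only the slope of this covariate, not its
distribution.

## Rendering

`renderBScan()` draws one eye as a `height × 1024` grid (defaults: 480
rows, 5 µm/pixel axial, 1024 A-scans on a 3.46 mm circle). Geometry per
column angle $\theta$ (degrees, temporal at 0°, superior at 90°; left
eyes mirrored so the temporal meridian is at 0° for both eyes):

* ILM at row $140 + 8\sin\theta$ — a gentle undulation so segmentation
  cannot exploit a flat boundary;
* pRNFL posterior boundary at ILM + thickness/axialScale, where the
  thickness profile is a smooth double-hump curve (two von-Mises-shaped
  bumps at the superior and inferior poles, concentration 2, amplitude
  0.9) multiplied by a periodic per-sector gain; the gains are fitted by
  a multiplicative fixed-point iteration so each sector's mean thickness
  equals the subject's truth to < 10⁻⁶ µm;
* RPE inner edge 280 µm below the ILM, RPE outer edge 40 µm deeper.

Reflectivities: vitreous 25, pRNFL = the subject's sector grayscale truth
(constant within a sector), inner retinal composite 110, RPE = the
subject's RPE grayscale truth, below-RPE 55. Pixels are reflectivity
times unit-mean multiplicative gamma speckle (shape 40 by default,
emulating a frame-averaged clinical scan; `Inf` disables speckle), then
clipped to [0, 255] and rounded to 8 bits. A `GroundTruth` sidecar
records the exact fractional boundaries and per-column reflectivities.

Boundary convention everywhere in the package: a layer owns the pixel
rows in the half-open band `[ceiling(upper), ceiling(lower))`. This
prevents double counting at shared boundaries and makes the sector
decomposition close exactly under pixel counts.

Per-eye speckle seeds derive from the master seed by a stated splitting
rule (`deriveEyeSeed()`), so any eye is reproducible in isolation.

## Quality degradation

`degradeQuality()` maps an image-quality knob `q` (calibration range
[40, 70]) to zero-mean additive Gaussian noise with
$\sigma = 24\,(70 - q)/30$; at the calibration maximum the image is
returned bit-identical. The noise is deliberately *mean-preserving*: the
association between image quality and measured grayscale already lives in
the generative linear model (slope 0.658), and attenuating tissue contrast
during degradation would double-count that effect and bias the
quality slope away from its generative value. The degradation therefore
models acquisition noise only; the systematic brightness effect of device
signal strength is a cohort-level property of the generator.

# Segmentation

`segmentBoundaries()` finds the four traces sequentially, each as a
minimum-cost left-to-right path by dynamic programming, with column-to-
column jumps limited to `maxJump` (default 3) rows and penalised by
`lambda` per row. The stages:

1. **ILM**: dark→bright signed vertical gradient, full admissible band.
2. **RPE inner edge**: dark→bright gradient, restricted to at least
   40 µm below the ILM.
3. **pRNFL posterior boundary**: *not* a gradient path. Each column's
   cost at candidate row $r$ is the residual of the best two-segment
   piecewise-constant fit of the intensities between the ILM and the RPE
   inner edge, split at $r$ (normalised per pixel). This changepoint
   estimator uses every pixel of the column and is far more robust to
   speckle outliers than any single-row gradient: spurious bright/dark
   speckle edges inside the pRNFL systematically attracted a gradient
   path, biasing the boundary vitread by up to ~1 px, while the
   changepoint cost reduced the bias to under 0.1 px.
4. **RPE outer edge**: bright→dark gradient below the RPE inner edge.

Band restrictions guarantee the ordering invariant
`ilm ≤ rnflPost ≤ rpeInner ≤ rpeOuter` by construction. Cost ties break
toward the smaller (vitread) row, so results are bit-reproducible; with
`maxJump` and integer images, the path is a pure function of the pixels.

The integer row found by the DP is the first row of the deeper layer, so
the continuous boundary lies in $(r-1, r]$; the refined estimate is
$r - 0.5$ plus the vertex offset of a parabola through the signed
gradient at rows $r-1, r, r+1$, clamped to $[-0.45, 0.45]$ so that
`ceiling(boundary)` remains $r$ and the half-open band convention is
unaffected by refinement. (The changepoint trace uses the flat $r - 0.5$
estimate; its cost is not a peaked function suitable for parabola
fitting.)

`lambda = 20` is the default smoothness penalty. It was chosen from a
scan against rendered ground truth across quality levels 45–65:
pooled mean absolute error 0.31–0.39 px and posterior-boundary bias
under 0.1 px, monotonically better than smaller penalties, with the
noise-free worst-column error at 0.5 px. A median 3×3 pre-filter
(`denoiseBScan()`) precedes segmentation in the pipeline.

A structureless image (maximum absolute gradient below `minGradient`)
raises a `prnflSegmentationFailure` error — a distinct condition class,
deliberately separate from QC *flagging*, which is a successful
segmentation judged implausible.

## Quality control

`flagMisidentification()` applies three deterministic rules standing in
for the human inspection used in clinical studies: median pRNFL thickness
outside [30, 250] µm; any trace rougher than a mean absolute second
difference of 2 px; mean pRNFL-band intensity not above the vitreous
background. Any firing rule flags the scan; flagged eyes are excluded
from analyses (and `measureEye()` refuses them unless overridden).

# Quantification

`columnAngle()` maps the 1024 columns to angles (column 1 = 0°,
temporal); left eyes are mirrored. `sectorOfAngle()` assigns the six
half-open sectors: temporal [315°, 45°), superior-temporal [45°, 90°),
superior-nasal [90°, 135°), nasal [135°, 225°), inferior-nasal
[225°, 270°), inferior-temporal [270°, 315°). Sector membership is by
column-center angle; no partial-column splitting (worst case one column,
0.35°).

`layerGrayscale()` is the pixel-weighted mean over the half-open band —
pixel weighting (not per-column averaging) is what makes
`gray_mean` equal the pixel-count-weighted mean of the six sector values
exactly. `layerThickness()` is the column mean of
`(lower − upper) × axialScale`. The average is taken over all 1024
columns (the full 360°).

Because thicker sectors contribute more pixels, the pixel-weighted
`gray_mean` sits ≈ 0.14 gray levels above the unweighted sector-offset
average under the default truth pattern — an intentional, documented
consequence of the convention, well inside the 1-gray-level acceptance
tolerance.

## Image-quality proxy

`computeImageQ()` measures a noise-to-signal ratio
$r = \mathrm{MAD}(\text{background}) / (p_{99.5} - \mathrm{median}
(\text{background}))$, with the background taken from the top 40 (vitread)
rows, and maps it affinely to quality units: $q = A + B\,r$. The
constants $A = 73.5456$, $B = -260.0229$ were frozen once from a
calibration experiment — 10 rendered eyes × 3 seeds degraded to knob
values 45 and 65, solving the two-anchor affine map — and verified
independently: knob 55 recovered as 55.5 averaged over 50 seeds
(tolerance ±2), noise-free scans score 66.8 (≥ 65), a pure-noise image
scores far below the usability gate of 45, and the proxy is strictly
monotone in the knob across the five levels 45–65.

# Statistics layer

* `ageGroupSummary()`: mean ± sample SD of all 14 parameters per age bin
  (default edges 18, 30, 40, 50, 60, 70, ∞) plus a Total row; empty bins
  report `n = 0` with `NA` moments rather than erroring.
* `compareSectors()`: paired t-tests on the within-eye differences of all
  15 sector pairs, Bonferroni-adjusted over the full family
  (`p_adj = min(1, 15p)`); zero-variance pairs are reported degenerate
  with `NA` p-values. The `nasal_all_significant` attribute records
  whether the nasal sector is significantly lower than each other sector
  at adjusted p < 0.001.
* `univariableScreen()`: one simple regression per covariate; the
  standardized coefficient equals the Pearson correlation; `p < 0.05`
  marks carry-forward.
* `multivariableFit()`: OLS on carried-forward ∪ forced covariates
  (axial length forced by default, mirroring designs that include it on
  physiological grounds regardless of the screen); a rank-deficient
  design errors naming the collinear columns.
* `iccTwoObservers()`: ICC(2,1) — two-way random effects, absolute
  agreement, single measurement — computed from the ANOVA mean squares:
  $\mathrm{ICC} = (MS_R - MS_E)\,/\,(MS_R + MS_E + \tfrac{2}{n}(MS_C -
  MS_E))$ for two observers.

# Pipeline

`runPipeline()` executes synthesize → degrade → denoise → segment → QC →
measure → analyze. Exclusion accounting mirrors a clinical reading
workflow, in order: manual `motion_artifact` flags, the quality gate
(`imageq ≤ 45` excluded), then automated boundary-misidentification
flags. The manifest asserts
`recruited = analyzed + Σ exclusions` on every run, and reruns with the
same configuration and seed are byte-identical. Problem sizes (397 eyes,
480 × 1024 scans) are the package's default working point, chosen so a
full cohort runs in about two minutes on one CPU.

```{r pipeline, eval = FALSE}
cfg <- pipelineConfig(n = 397, outDir = "out")
res <- runPipeline(cfg)
res$manifest
```

# What the generator does and does not emulate

Emulated: sectoral grayscale/thickness anatomy (double-hump profile,
nasal-lowest grayscale), multiplicative speckle of a frame-averaged scan,
device-style quality gating and additive acquisition noise, the linear
determinant structure of the average grayscale value, left/right-eye
mirroring, 8-bit quantization.

Not emulated: optical attenuation physics, vessel shadows, motion
artifacts (only a manual flag field), volumetric data, correlated
covariates, the proprietary formulas of any device's quality factor or
segmentation ("ASAP"-style software); the segmentation here is a
transparent stand-in, not a reproduction.

# Numerical and degenerate-input conventions

* Ties in DP path costs break toward the smaller row; the tie tolerance
  is 10⁻¹².
* `n = 0` cohorts, empty age bins, and constant covariates are handled
  (empty frame, `n = 0` rows, not-estimable flags) rather than erroring;
  genuinely impossible requests (negative `n`, violated variance budget,
  empty measurement band, rank-deficient design, structureless image)
  raise typed errors.
* Boundary CSVs, ground-truth JSON and cohort CSVs round-trip exactly
  within write precision; images round-trip bit-exactly through PNG
  (lossless). JPEG is not supported by the installed image stack; PNG and
  TIFF are.
* All randomness flows from one master seed through stated derivation
  rules; no stage consults the wall clock or ambient RNG state except
  where documented (`degradeQuality()` draws from the current RNG stream;
  the pipeline seeds it per eye).
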