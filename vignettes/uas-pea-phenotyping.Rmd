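---
title: "Plot-level pea phenotyping from UAS imagery: methods and design"
author: "uasPheno authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plot-level pea phenotyping from UAS imagery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uasPheno)
```

## The problem

Pea breeding programs evaluate hundreds of small field plots for above-ground
biomass (AGBM), flowering time, lodging and related traits. Direct
measurement of AGBM is destructive and slow; drone (UAS) imagery offers a
non-destructive proxy. This package implements the image-analysis side of
that workflow as a tested pipeline:

1. **Radiometric correction** of a five-band (B/G/R/RE/NIR) orthomosaic
   against a white reference panel of known reflectance.
2. **Vegetation indices** per pixel: GRVI = (G−R)/(G+R),
   NDVI = (NIR−R)/(NIR+R), NDRE = (NIR−RE)/(NIR+RE), and
   NIRv = NIR·NDVI − 0.08 (soil-resistant variant; the
   (NDVI−0.08)·NIR form is available behind a flag).
3. **Canopy structure** from elevation: a digital terrain model (DTM) is
   interpolated from bare-soil elevations and subtracted from the digital
   surface model to give the crop surface model, CSM = DSM − DTM (height
   above ground). Pixels with CSM strictly above a threshold (default
   0.15 m) are canopy; per plot, canopy height CH is the mean CSM over
   canopy pixels, canopy coverage CC is the canopy-pixel count times the
   pixel area, and plot volume PV = CH × CC.
4. **Zonal statistics** per plot polygon (sum as absolute vigor, mean as
   relative vigor), optionally soil-masked by the canopy mask.
5. **Trait models**: Pearson correlation reports against ground truth
   (entry-mean or plot-wise protocols), a two-date lodging score
   (CH₁ − CH_k) × (CC₁ − CC_k), a one-dimensional green-band leaf-type
   classifier, and Lasso AGBM estimation on standardized features, with
   frozen literature presets of the published winter/spring equations.
6. **Georeferencing QC**: horizontal position error as the RMS of
   easting/northing GCP errors, and vertical position error from
   elevation-change differences along a transect.

Because real field imagery is not shippable, the package's first-class
`synthetic_field` module generates randomized-complete-block trials with
known per-plot ground truth and renders them into band stacks and DSMs, so
that every downstream stage can be validated against what was simulated.

## The synthetic trial generator

The generator is the package's statement of the study conditions; its
defaults are fixed and the test suite runs against them.

**Layout.** `generateTrialLayout()` builds an RCBD: each replicate is a row
of 1.5 m × 5.0 m plots separated by 0.5 m alleys, with the entry order in
each block a seeded random permutation.

**Growth.** Canopy height and cover follow a unimodal beta-shaped curve in
accumulated degree days (ADD, base 0 °C), rising to a peak at 1268 ADD
(flowering in the winter-trial calendar) on a 0–2200 ADD season and
declining toward maturity. The reference dry-matter curve this emulates is
known only qualitatively, so the curve family is shape-matched, not fitted.
Entry-level peak height is drawn from N(0.70, 0.08) m and peak cover from
N(0.85, 0.06) (truncated), with small replicate-level jitter — values
chosen once as typical of winter pea canopies at flowering and tall enough
that lodged canopies stay above the 0.15 m segmentation threshold.

**Reflectance.** Canopy and soil have fixed per-band reflectances chosen so
that GRVI(soil) < 0 < GRVI(canopy) — early-season soil exposure therefore
dilutes unmasked vegetation indices, reproducing the documented
soil-brightness distortion. Leaf type is an entry-level trait: semi-leafless
(af) entries have higher mean green reflectance (0.135) than normal (Af)
entries (0.105), with 0.010 SD per plot, a ~3 SD separation consistent with
the ~90% classification accuracies reported for this kind of data.

**AGBM link.** True per-plot AGBM (kg fresh weight) is linear in the latent
canopy state the image features measure: intercept 2 + 4·cover +
8·height·cover + N(0, 0.3). The residual SD of 0.3 kg (≈4% of a typical
8 kg plot) represents a favorable, low-noise phenotyping regime; field
campaigns are noisier, which is why published validation correlations
(≈0.6) are lower than what these synthetic trials achieve (≥0.9). Passing
tests therefore demonstrate correctness of the pipeline, not field-level
accuracy.

**Lodging.** A seeded fraction of plots lodges after the growth peak: height
is multiplied by the plot's lodging ratio (canopy height / plant length;
1 = erect; lodged plots draw 0.6–0.85, erect plots 0.92–1.0) and cover
rebounds above the plot's peak cover instead of senescing, reflecting a
collapsed canopy spreading on the ground. This gives the two-date lodging
score its discriminating sign: erect plots have falling cover and moderate
height loss (positive score), lodged plots have rising cover and strong
height loss (negative score).

**Rendering.** Pixels inside a plot are canopy with probability equal to the
plot's cover fraction (independent Bernoulli per pixel), making measured
canopy coverage an unbiased estimator of cover. Terrain is a gentle plane
(default 1% west-east grade) so DTM interpolation is non-trivially
exercised. Per-band Gaussian noise (default SD 0.01 reflectance units) and
elevation noise (default 0.005 m) are added, and the DSM is quantized to
1 mm — the "elevation quantum" that bounds achievable height recovery. The
default ground sample distance is 0.05 m so that a 60-plot trial renders in
seconds; the 0.005 m GSD of centimeter-grade UAS surveys is exercised in
unit tests on small grids (pixel area 25 × 10⁻⁶ m²).

**What the generator does not emulate:** photogrammetric stitching artifacts,
view-angle/BRDF effects, within-plot row structure, weeds, wind-blurred
canopies, and spatially correlated sensor noise. Real-data performance
therefore cannot be inferred from the synthetic recovery rates; the
synthetic scenes establish that the formulas, masking, zonal accounting and
model protocols are implemented correctly.

## Numerical and design choices

- **Pixel membership** is pixel-center-in-polygon with half-open pixel
  extents, so zonal statistics are deterministic and additive over polygon
  partitions. Coordinates are abstract projected easting/northing in
  metres; no CRS handling or reprojection.
- **Rasters** are stored as ESRI ASCII grids (one text file per band, with a
  JSON sidecar naming a five-band stack) at full double precision, making
  fixtures diffable and round trips lossless. Vector layers are GeoJSON.
- **DTM interpolation** is an exact thin-plate-spline interpolant of
  bare-soil elevations: it passes through every soil sample and reproduces
  planar terrain exactly, and it is defined everywhere without a
  triangulation hull. Soil samples are capped at 250 (deterministic
  even subsample) to keep the solve small; by default soil pixels are those
  outside all plot polygons, and a user-supplied soil mask overrides.
- **Canopy threshold** comparisons are strict (>), so the 0.15 m boundary
  case is deterministic. The threshold is an empirical configuration value,
  not a fitted quantity.
- **CH statistic**: mean CSM over canopy pixels (so PV = CH × CC
  approximates the integral of height over covered area); max or a
  quantile are available via `chStat`.
- **Division-by-zero pixels** in the normalized-difference indices become
  nodata, never ±Inf, so downstream zonal sums stay finite.
- **VI zonal statistics** are soil-masked by default (the canopy mask
  doubles as the soil mask); the unmasked mode is first-class because the
  choice is consequential at early growth stages, and which mode fed the
  published correlation tables is not stated.
- **Pearson p-values** are two-sided via the t distribution (n − 2 df), with
  stars at 0.05/0.01/0.001. Entry-mean and plot-wise protocols are both
  provided; with one replicate per entry they coincide (tested).
- **HPE** is implemented as the RMS horizontal error
  √(Σ(EE² + NE²)/n) — the printed formula is typographically ambiguous, and
  RMS is the standard horizontal accuracy metric at the reported
  magnitudes. **VPE** is signed, (ΔZ_R − ΔZ_NR)/n with ΔZ the summed
  absolute adjacent elevation changes (4 segments by default); the absolute
  value is reported alongside since published tables list magnitudes
  without a sign convention.
- **Lasso protocol**: features are centered and scaled on the matched
  dataset (the standardization is frozen into the fitted model); a single
  seeded 85% split forms the training set; the L1 penalty is chosen by
  5-fold cross-validation (seeded folds) over an explicit logarithmic
  penalty grid spanning six decades below the null-model λ — an explicit
  grid because path early-exit heuristics otherwise truncate the search on
  nearly noiseless data; validation (Pearson r, MAE) is against the
  complete dataset. Split fraction and fold count are both exposed.
- **Frozen presets** of the published winter (divisor 1.5 × 10⁴) and spring
  (divisor 10³) AGBM equations are applied to features standardized on the
  current dataset, because the originating trial's feature means/SDs are
  unpublished; absolute estimates are therefore not comparable to the
  original ones, rankings are. The printed coefficients (including the
  duplicated 4.98 for spring NDVI-mean and NDRE-sum, and the unexplained
  divisors) are shipped verbatim.
- **Lodging score** keeps its printed sign convention (it can be negative);
  correlations against lodging ratio are reported signed.
- **Leaf-type threshold** is an exhaustive search over midpoints of
  consecutive sorted training values, minimizing training error, ties
  broken toward the lower threshold; training accuracy is invariant under
  monotone transforms of the green means (tested).
- **Randomness**: every operation draws from a named sub-stream derived
  from one top-level seed, so any stage can be re-run in isolation and
  whole runs are byte-reproducible (`runPipeline` manifests record the
  config fingerprint and seed).

## Problem sizes

The test suite and acceptance script use a 20-entry × 3-replicate trial
(60 plots) across the five winter imaging timepoints (365, 784, 1268, 1725,
1948 ADD) at 0.05 m GSD — about 0.4 Mpixel per band per scene — as the
standard end-to-end scene, with smaller trials (4–10 plots, 1–3 timepoints)
for unit-level recovery checks and 16×16–64×64 random grids for formula
oracles. Lasso protocol checks use n = 180 rows (60 plots × 3 timepoints
worth of data) and n = 300 for the null-shrinkage check.

## Known limitations

- No CRS support, reprojection, or shapefile parsing; GeoJSON and ASCII
  grids only.
- The DTM extrapolates the thin-plate spline outside the soil-sample hull;
  on strongly non-planar terrain with sparse soil support this can drift.
- Panel correction is a single global gain per band — no vignetting or
  per-pixel illumination model.
- The lodging score is a two-date contrast; it does not model partial or
  recovering lodging trajectories.
- Preset AGBM equations produce dataset-relative estimates (see above).

## A short worked example

```{r example, eval = FALSE}
layout <- generateTrialLayout(6, 2, seed = 1)
truth  <- generateTruth(layout, c(784, 1268, 1725), seed = 1)
scene  <- renderScene(truth, layout, SceneSpec(), 1268, seed = 1)

stack <- panelCorrect(scene$stack, scene$panel)
dtm   <- buildDTM(scene$dsm, plots = layout)
csm   <- computeCSM(scene$dsm, dtm)
mask  <- segmentCanopy(csm, 0.15)
plotCanopyMetrics(csm, mask, layout)
```

The pipeline wrapper (`runPipeline`, or the `inst/cli/uaspheno` script)
chains these stages — simulate, extract, qc, traits, model — over a single
YAML config and writes CSV/GeoJSON/JSON artifacts plus a run manifest.
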