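# uasPheno

Plot-level plant phenotyping from unmanned-aerial-system (UAS) imagery for
pea breeding trials — radiometric correction, vegetation indices, crop
surface models, zonal statistics, trait models, and Lasso biomass
estimation, built as a tested, reproducible R pipeline.

## What it computes

Breeding programs assess above-ground biomass (AGBM), lodging, leaf type
and phenology on hundreds of small plots. From a five-band (B/G/R/RE/NIR)
orthomosaic and a surface model, this package extracts the standard image
features of that workflow:

- **Vegetation indices** per pixel:
  `GRVI = (G − R)/(G + R)`, `NDVI = (NIR − R)/(NIR + R)`,
  `NDRE = (NIR − RE)/(NIR + RE)`, and the soil-resistant
  `NIRv = NIR · NDVI − 0.08`, after each band is rescaled so the white
  reference panel (99% reflectance) reads its nominal value.
- **Canopy structure**: `CSM = DSM − DTM` (height above ground), a canopy
  mask at a strict 0.15 m threshold, and per plot the canopy height
  `CH` (mean CSM over canopy pixels), coverage `CC` (canopy pixels ×
  pixel area) and volume `PV = CH × CC`.
- **Zonal statistics** (sum, mean, n) over plot polygons, optionally
  soil-masked.
- **Trait models**: entry-mean or plot-wise Pearson correlation reports;
  the two-date lodging score `(CH₁ − CH_k) × (CC₁ − CC_k)`; a green-band
  leaf-type threshold classifier; Lasso AGBM estimation on standardized
  features (seeded 85% split, cross-validated penalty), plus the published
  winter/spring linear AGBM equations as frozen presets.
- **Georeferencing QC**: horizontal position error
  `HPE = sqrt(Σ(EE² + NE²)/n)` over ground control points and the
  transect-based vertical position error.

A first-class synthetic-field module (`generateTrialLayout`,
`generateTruth`, `renderScene`) builds randomized-complete-block trials
with known ground truth and renders them into band stacks and DSMs, so the
whole pipeline is testable end to end without field data. Rasters are
plain-text ESRI ASCII grids, vectors are GeoJSON, tables are CSV.

## Worked example

Simulate a 6-entry × 2-replicate trial, render the flowering-time scene,
and extract canopy metrics:

```r
library(uasPheno)

layout <- generateTrialLayout(6, 2, seed = 1)          # 12 plots, 1.5 x 5 m
truth  <- generateTruth(layout, c(784, 1268, 1725), seed = 1)
scene  <- renderScene(truth, layout, SceneSpec(), 1268, seed = 1)

stack <- panelCorrect(scene$stack, scene$panel)        # panel -> 0.99
dtm   <- buildDTM(scene$dsm, plots = layout)           # terrain from alleys
csm   <- computeCSM(scene$dsm, dtm)
mask  <- segmentCanopy(csm, 0.15)
head(plotCanopyMetrics(csm, mask, layout), 4)
#>   plot_id ch_uas   cc   pv n_canopy
#> 1    P001  0.751 6.11 4.58     2442
#> 2    P002  0.711 6.34 4.51     2536
#> 3    P003  0.712 6.68 4.76     2673
```

`ch_uas` is the plot's canopy height in m (the simulated truth for P001 was
0.750 m at 82% cover), `cc` its covered area in m² of the 7.5 m² plot, and
`pv` the canopy volume in m³. Correlating the elevation-derived features
against the simulated AGBM with the entry-mean protocol:

```r
t0  <- subset(truth, add == 1268)
met <- merge(plotCanopyMetrics(csm, mask, layout),
             data.frame(plot_id = t0$plot_id, entry = t0$entry))
correlateTraits(met, t0[c("plot_id", "agbm")], c("ch_uas", "cc", "pv"),
                "agbm", grouping = "by_entry_mean")
#>   feature trait    r      p stars n
#> 1  ch_uas  agbm 0.55 0.2595       6
#> 2      cc  agbm 0.49 0.3191       6
#> 3      pv  agbm 0.95 0.0031    ** 6
```

Plot volume — the height × coverage product — tracks biomass most closely,
as expected for a trait that integrates canopy size.

The same stages run as pipeline subcommands over a YAML config, writing
rasters, tables, model JSON and a run manifest under one directory:

```sh
Rscript inst/cli/uaspheno simulate --out run --seed 11
Rscript inst/cli/uaspheno extract  --out run --seed 11
Rscript inst/cli/uaspheno model    --out run --seed 11
```

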