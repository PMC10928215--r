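---
title: "Mapping forest aboveground biomass from LiDAR heights and multi-sensor covariates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping forest aboveground biomass from LiDAR heights and multi-sensor covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agbmapr)
```

## The estimation problem

Spaceborne LiDAR measures forest height in sparse ~65 m footprints; field
plots calibrate a height-to-biomass allometry; imaging sensors (L-band and
C-band SAR, optical reflectance, terrain) see every pixel but saturate with
increasing biomass. A wall-to-wall aboveground-biomass (AGB) map therefore
chains three models:

1. **Allometry.** Per-tree biomass `W = 0.1355 (D²H)^0.817` (kg; DBH in cm,
   height in m, census threshold DBH ≥ 5 cm) is summed per plot and scaled
   to Mg ha⁻¹; plot structure is summarized by Lorey's height, the
   basal-area-weighted mean height, which up-weights the large trees that
   carry most biomass. A regional power law `AGB = a·L^b` links the two.
   Two regions (north, south) get independent fits; the generating values
   used throughout the synthetic studies are `a = 0.5014, b = 1.8762`
   (north) and `a = 0.1237, b = 2.3281` (south).
2. **Footprints to cells.** LiDAR Lorey's heights are converted to AGB with
   the regional models and averaged within grid cells containing at least
   two footprints, suppressing the large per-footprint height error
   (sd 5.9 m). Footprints on slopes > 15°, or 12–15° with AGB ≤ 40 Mg ha⁻¹,
   are excluded; heights are capped at 25 m.
3. **Extrapolation.** Regression forests trained on the cells (60 % train /
   40 % validation) predict AGB from the covariate stack at every forest
   pixel, separately for flat terrain (slope ≤ 10°), rugged terrain and the
   C-band coverage gap, and the three maps are stitched. A binned
   zero-intercept regression corrects the forests' range compression.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| calibration factor CF | −83.0 | dB | L-band mosaic DN → γ⁰ |
| focal-mean radius | 150 | m | speckle suppression before calibration |
| min C-band observations | 2 | — | below it a pixel joins the gap stratum |
| cover threshold | 10 (strict >) | % | year-2000 canopy baseline for the forest mask |
| slope limits | 12 / 15 | ° | footprint exclusion rules |
| conditional AGB limit | 40 | Mg ha⁻¹ | low biomass on moderate slopes is unreliable |
| height cap | 25 | m | taller Lorey's heights are essentially absent |
| cell size | 400 | m | aggregation cell (see below) |
| min footprints per cell | 2 | — | cells driven by one shot are discarded |
| stratum slope split | 10 | ° | flat vs rugged models |
| train fraction | 0.6 | — | evaluation on the held-out 40 % |
| pruned variables | 10 | — | smallest node-purity features dropped per model |
| bias-correction bin | 10 | Mg ha⁻¹ | reference-axis bin width |
| carbon fraction | 0.47 | Mg C / Mg | biomass-to-carbon conversion |
| site-filter thresholds | 0.5 / 0.15 / 2 / 0.25 | —, —, dB, — | forest fraction (≥), NDVI and SAR fluctuation (<), heterogeneity ratio (≤) |

The real method aggregates into 0.01° (~1 km) cells. The synthetic scenes
live on a planar 50 m grid, and we use a 400 m cell (8 × 8 pixels) so that
a 200 × 200 px scene yields ≈ 500 usable cells — the same cells-per-scene
regime at a scale where the whole pipeline runs in seconds. The cell size
is configurable (`pipeline_config(cell_size_m = ...)`), and the aggregation
logic is scale-free.

## The synthetic-scene generator

`generate_scene()` builds the statistical structure the analysis assumes,
not a physical simulation:

- **Latent AGB surface.** White noise is circularly convolved with a
  Gaussian kernel (sd = `corr_length` pixels, FFT), standardized, and
  mapped onto the configured range through a probability-integral
  transform, giving a smooth field with an approximately uniform marginal
  over 0–250 Mg ha⁻¹ — a landscape that spans sparse woodland to dense
  forest rather than clustering mid-range.
- **Sensors.** Every covariate responds through the saturating family
  `y = c₀ + c₁(1 − exp(−AGB/k))` plus noise: multiplicative (log-scale)
  speckle on L-band linear power, additive dB noise per C-band observation,
  additive reflectance noise per optical observation, with per-observation
  cloud flags. The HV−HH ratio saturates later than either polarization
  (larger k), and the C-band response is weak — matching the qualitative
  sensor behaviour the method relies on.
- **Terrain and masks.** A smooth DEM (relief 800 m by default) produces
  both flat and rugged terrain on every scene; canopy cover saturates
  quickly in AGB so sparse pixels fall out of the forest mask; a smooth
  blob of under-observed C-band pixels (10 % of the scene) creates the
  no-C-band stratum large enough to train its own model.
- **Footprints and plots.** Footprint heights invert the generating
  allometry at the pixel's true AGB and add Gaussian error (sd 5.9 m,
  floored at 0). Field plots are constructed so Lorey's height and plot
  AGB sit exactly on the target power law up to a configurable
  multiplicative scatter: all trees in a plot share the target height and
  the diameter scale solves the biomass sum in closed form, which makes the
  zero-scatter campaign exactly identifiable — the property the
  acceptance tests exploit.

What the generator does **not** emulate: orbit geometry, waveform physics,
sensor point-spread functions, geolocation error, mixed pixels,
topographic shadowing, or regionally varying allometry. Passing tests
therefore demonstrate that the pipeline's logic is correct and its
statistical behaviour (skill under the assumed noise, bias-correction
geometry, filter semantics) is as designed — not that the method achieves
any particular accuracy on real archives.

## Numerical and design choices

- **Allometry fit scale.** `AGB = a L^b` is fitted by Levenberg–Marquardt
  nonlinear least squares on the original Mg ha⁻¹ scale (log–log OLS gives
  the start values), so the reported RMSE is in Mg ha⁻¹ and large plots are
  not down-weighted as a log fit would do.
- **Speckle-filter domain.** The focal mean is applied to linear power and
  converted to dB afterwards; averaging dB values would bias backscatter
  low.
- **Cap, then convert, then average.** Heights are capped at 25 m at the
  footprint level before conversion, and cell AGB is the mean of converted
  footprints (the allometry is nonlinear, so averaging heights first gives
  a different, smaller value). Both alternatives remain available
  (`agb_from = "cell_mean_height"`).
- **Bias correction as a global rescale.** The corrector divides by the
  zero-intercept slope of the bin means. This is the unique monotone
  linear map that makes the refitted bin regression coincide exactly with
  the 1:1 line, and it is idempotent; per-bin inversion would be neither.
- **R² convention.** Squared Pearson correlation of predicted vs reference
  (the scatter-plot convention); the 1 − SSE/SST variant is available via
  `r2_method = "sse"`. Zero reference variance yields `NA`, reported as
  such.
- **Boundary semantics.** "More than 10 % cover" and "more than 15° slope"
  are strict; fluctuation limits 0.15 and 2 dB are strict; "at least half
  forest" and "ratio > 0.25 removed" are inclusive on the passing side. A
  site with zero AGB has an undefined heterogeneity ratio and is excluded
  with a distinct audit code.
- **Forest hyperparameters.** 500 trees, `mtry = ⌈p/3⌉`, impurity ("node
  purity") importance, fixed seed, single-threaded prediction for
  determinism. Pruning drops the 10 lowest-importance features with stable
  input-order tie-breaking. The no-C-band model uses the identical
  procedure minus the three C-band features.
- **Scale mismatch.** Models are trained on cell-mean covariates and
  applied to 50 m pixels. This mismatch is part of the method's design and
  is kept, not "fixed"; cell-level evaluation (pixel predictions averaged
  per cell) is the honest skill measure.
- **Fluctuation.** Temporal stability quantities are max − min over the
  annual series of buffer means.
- **Raster I/O.** Scenes and maps are written as one 32-bit float TIFF per
  band with a JSON sidecar carrying the grid origin, pixel size and
  per-band value scaling; the synthetic frame is planar (metres), so no
  geodesic machinery is involved.

## Problem sizes and what the tests compute

The default study is a 200 × 200 px (10 km × 10 km) scene, ≈ 500 usable
cells, ≈ 2 600 footprints (mean ≈ 4 per cell), three forests of 500 trees
each; a full run takes ~15 s on one CPU. The test suite checks, among
other properties: exact worked values of every closed-form equation;
exact identifiability of the allometry from zero-scatter plots and
recovery within pre-computed 200-replicate Monte-Carlo intervals under
20 % scatter; agreement of focal mean, temporal statistics, compositing,
aggregation, histogram and metric computations with brute-force oracles;
the exact survivor set of a constructed 20-site filter table including all
four threshold boundaries; held-out cell-level R² ≥ 0.5 across ten seeds
of the default study; bin-regression slope exactly 1 after correction;
and near-exact recovery (R² ≥ 0.98) of the true surface when every noise
source is switched off.

## Known limitations

- The synthetic sensors share one saturation family; real sensor–biomass
  relationships differ in form, and real speckle is not log-normal.
- Region labels (north/south) are a scene attribute; no latitude-threshold
  assignment is exercised beyond the labels.
- The pipeline publishes no uncertainty raster, matching the method it
  implements.
- Comparison statistics (histograms, 1 km boxplot summaries, carbon
  totals) are demonstrated on synthetic maps; no third-party reference
  rasters ship with the package.
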