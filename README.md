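# benthoscape

Benthic habitat mapping from the three products of a multibeam echosounder
(MBES) survey: **bathymetry**, the **backscatter mosaic**, and the
**backscatter angular response** (AR). The package is aimed at marine
habitat-mapping practitioners who have calibrated per-beam backscatter
samples, a bathymetry grid and ground-truth observations (e.g. towed-video
biota classes) and want a supervised habitat map together with an honest
account of which acoustic variables drive it.

## What it computes

The pipeline integrates all three MBES data sources in one Random-Forests
classification:

1. **Mosaic** — the angular dependence of per-beam backscatter levels
   `BS(θ)` is statistically compensated with a sliding window of 25
   consecutive pings and a reference angle of 30°
   (`BS' = BS − mean_window(BS | θ) + mean_window(BS | θ_ref)`), then gridded
   at 2.5 m into a dB mosaic and an 8-bit version for texture analysis.
2. **Segmentation** — region growing from single-pixel seeds, recursively
   merging the adjacent regions of most similar mean grey level under a
   threshold that relaxes up to a user value (default 1), then absorbing
   regions below an area threshold (survey-scale default 2500 px).
3. **AR features** — per segment, one mean angular-response curve is compiled
   from the *pre-normalization* samples (dB-space mean per 1° bin), and four
   statistics are taken over 30–50° incidence angles: mean, least-squares
   slope, skewness and kurtosis, then rasterised back onto the grid.
4. **Derivatives** — six terrain layers from bathymetry (slope, aspect,
   rugosity, maximum curvature, BPI, complexity) and six mosaic layers (HSI
   red/green/blue composites; GLCM homogeneity, entropy and correlation over
   7×7 windows averaged across the 0/45/90/135° directions).
5. **Classification** — a random forest (`ntree = 200`,
   `m = floor(sqrt(p))`) on the co-registered 18-layer stack, with scaled
   variable importance, the two-rule incremental feature-selection procedure
   (≤3 variables added at a time; importance spread within an addition
   < 0.2), and accuracy assessment: error matrix, overall accuracy, Kappa
   `κ = (θ₁ − θ₂)/(1 − θ₂)` with its delta-method variance, and pairwise
   `Z = |κ_a − κ_b| / sqrt(var_a + var_b)` tests (critical value 1.96).

A synthetic-survey module generates a complete, seeded study area (bathymetry
with trend and bumps, depth-band × substrate habitat map, per-beam samples
with class-specific angular response, per-line gain artefacts, ground-truth
transects) so the whole pipeline is testable without any field data.

## Worked example

Simulate a 500 m × 500 m world (200×200 cells at 2.5 m), build the 18-layer
stack, and compare a model without AR features against the full model:

```r
library(benthoscape)
res <- run_recovery_experiment(sim_config(seed = 1))
head(res$importance, 6)
#>        variable        raw    scaled
#> 1    bathymetry 0.22181362 1.0000000
#> 2       ar_mean 0.11588365 0.5224370
#> 3        mosaic 0.07729578 0.3484718
#> 4      hsi_blue 0.05462732 0.2462758
#> 5 max_curvature 0.04938045 0.2226214
#> 6       hsi_red 0.04504950 0.2030962
res$run_without_ar
#> ModelRun: 14 variables; overall accuracy 97.2%, kappa 0.962
res$run_with_ar
#> ModelRun: 18 variables; overall accuracy 99.3%, kappa 0.991
z <- z_test(res$run_without_ar$matrix, res$run_with_ar$matrix)
#> Z = 1.36 (not significant at 95%)
```

Bathymetry and the AR mean lead the importance ranking, and adding the four
AR features raises held-out accuracy — the qualitative behaviour expected
when habitat class is driven jointly by depth and substrate, with the mosaic
degraded by residual line artefacts that the per-segment AR curves average
out. `select_features(res$importance)` returns the nested variable subsets
produced by the two addition rules, ready for `run_model()`.

A command-line driver with `simulate` / `mosaic` / `segment` / `arfeat` /
`evaluate` subcommands is installed at `inst/cli/benthoscape.R`
(`Rscript inst/cli/benthoscape.R segment --mosaic mosaic.asc --similarity 1
--min-area 2500 --out-dir out`). Rasters are exchanged as ESRI ASCII grids or
single-band uncompressed GeoTIFFs; samples and ground truth as CSV; segment
polygons as GeoJSON.

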