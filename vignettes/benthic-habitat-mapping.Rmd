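---
title: "Mapping benthic habitats from multibeam bathymetry, mosaic and angular response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping benthic habitats from multibeam bathymetry, mosaic and angular response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(benthoscape)
```

## The problem and the model

A multibeam echosounder survey yields three kinds of information about the
seabed. *Bathymetry* constrains where biological communities can live (light,
wave exposure, current). The *backscatter mosaic* is a grey-level image of
acoustic reflectivity after the systematic dependence of backscatter on
incidence angle has been statistically removed; it resolves fine spatial
pattern but loses the quantitative angular information. The *angular response*
— backscatter level as a function of incidence angle `θ` — is diagnostic of
seabed type precisely because it is *not* normalized, but a useful mean curve
needs many pings, so its native spatial resolution is coarse.

`benthoscape` implements a pipeline that keeps all three: the mosaic is
segmented into homogeneous regions; one mean angular-response curve is
compiled per segment from the samples *prior to* angular compensation; four
statistics of each curve over the 30–50° band (mean, least-squares slope,
skewness, kurtosis) are attached to every pixel of the segment. This recovers
quantitative angular information at mosaic resolution. The resulting 18-layer
stack — bathymetry + 6 terrain derivatives, mosaic + 6 texture/composite
derivatives, 4 angular-response features — is classified by a random forest
against ground-truth observations, and the forest's variable importance
drives an incremental feature-selection procedure.

## Stages, parameters and their defaults

### Angular normalization and mosaic

For each sample, the mean level of its 1°-angle bin within a centred sliding
window of **25 consecutive pings** on the same survey line is subtracted and
the window's mean at the **30° reference angle** added back. On homogeneous
seabed this maps every sample to the local 30° level; between seabed types
the 30°-level contrast is preserved. The window is per-line (crossing line
boundaries would mix headings) and truncated at line ends. All averaging is
in dB space, for the mosaic as well: the angular-response curves are defined
as dB-domain means, and using a single domain keeps the two products
commensurable. Cell size defaults to **2.5 m**. 8-bit quantisation for
texture analysis maps the 1st–99th percentile range linearly onto 0–255
(rounded half-up, clipped); the upstream scaling used by the original
processing chain is not published, so the percentile rule is our choice and
is exposed as `lo_dB`/`hi_dB`.

Incidence angles are stored unsigned (port and starboard folded together).
The feature band 30–50° is used regardless of side, and the simulator
computes `θ` on a flat-seafloor approximation (steering angle = incidence
angle), mild in that band. `read_samples(fold_angles = FALSE)` rejects signed
input instead, for diagnostics.

### Segmentation

Region growing from single-pixel seeds: repeatedly merge the 4-connected
region pair whose pixel-count-weighted mean grey levels differ least,
provided the difference is under the current threshold; the working threshold
ramps geometrically (factor 2 per pass, default 4 passes) up to the final
**similarity threshold (default 1)** — "increasingly less stringent". A
second phase absorbs every region smaller than the **area threshold** into
its most similar neighbour. The cited survey-scale value is 2500; we read it
as *pixels* (≈15,600 m² at 2.5 m cells), which matches the segment scale
shown in the source material, and flag it here because the original software
does not document the unit. Region similarity as absolute mean difference and
the merged mean as the count-weighted mean are our choices (the cited
region-growing family does not fix a statistic); ties are broken by lower
segment id so output is fully deterministic. Nodata pixels belong to no
segment, and segments never span nodata.

### Angular-response features

Curves are compiled from **pre-normalization** levels: normalization destroys
exactly the information these features quantify. Samples are assigned to
segments by label-raster cell membership (never ambiguous at polygon edges).
Statistics are computed over the per-bin mean values, not the raw samples:
the features are attributes of the *curve*. The band is 30–50°, at least 5
populated bins are required, kurtosis is non-excess (Gaussian → 3), and a
zero-variance curve has undefined skewness/kurtosis (propagated as nodata).

### Terrain and texture derivatives

All operators emit nodata wherever their window touches nodata or the border.

* slope/aspect: Horn's 3×3 gradients; aspect is the azimuth of steepest
  descent (deepening, for depth-positive-down grids), nodata when flat.
* rugosity: surface area of the eight triangulated facets of the 3×3 window
  over planar area; exactly `1/cos(s)` on a plane of slope `s`.
* maximum curvature: local quadratic fit; default is the largest-magnitude
  principal curvature (Hessian eigenvalue), with profile/plan available —
  the original tooling does not document which it uses.
* complexity: the slope operator applied to the slope raster.
* BPI: cell elevation minus the mean over the annulus `inner < r ≤ outer`
  (both 10 cells by default; equal radii mean the ring within half a cell of
  that radius). Output stays in natural units (metres); the cited tool's
  integer scale factor is only a rounding flag here because its arithmetic is
  not defined in the source material.
* HSI red/green/blue: an 11×11 low-pass drives hue, the 3×3 high-pass
  magnitude drives intensity, saturation is fixed at 0.9, and the standard
  HSI→RGB sector transform emits 0–255 layers. The original band assignment
  is not published; the mapping is isolated in one function so it can be
  swapped.
* GLCM homogeneity/entropy/correlation: 7×7 windows, displacement 1,
  directions 0/45/90/135° averaged, symmetric counting, the full 0–255 grey
  range with no requantisation. Entropy uses the natural log (base only
  scales the layer). A constant window gives homogeneity 1, entropy 0 and —
  by the zero-variance convention — correlation 0.

### Classification and selection

The forest uses **200 trees** and `m = floor(sqrt(p))` candidate predictors
per split, grown to purity on bootstrap samples, majority vote with ties to
the lowest class id. Importance defaults to mean impurity decrease scaled to
a maximum of 1; the original study does not name its measure, and no
well-tested forest implementation exists in the target environment, so the
forest is implemented in compiled code behind the same contract and seeded
through R's RNG. The 70/30 train/test split is stratified per class.

Feature selection starts from the variables of scaled importance 1 and walks
down the ranking adding groups under two rules: at most 3 variables at a
time, and the spread of scaled importance within an added group below 0.2.
Variables at or below a floor of 0.05 are treated as negligible and never
added automatically — the original procedure stopped by judgement; we encode
the rules and keep the subset list inspectable.

### Accuracy assessment

Error matrices are predicted-rows × reference-columns (the convention is
fixed here because the source material never prints its matrices). Overall
accuracy, user's/producer's/mean per-class accuracy, and Kappa with the
standard four-term delta-method variance
(θ₁ observed agreement, θ₂ chance agreement, θ₃ = Σx\_ii(x\_i+ + x\_+i)/N²,
θ₄ = Σx\_ij(x\_j+ + x\_+i)²/N³) are computed from it, and models are compared
with `Z = |κ_a − κ_b|/√(var_a + var_b)` against 1.96. The Z test treats the
two samples as independent, as in the cited practice; when two models share
test points this is approximate, and we deliberately do not "fix" the cited
method. Layer redundancy is screened with pairwise Pearson R² over shared
valid pixels, flagging R² > 0.5.

## The synthetic world: what it emulates, and what a green test proves

The simulator states one explicit world (defaults in `sim_config()`):

* 500 m × 500 m at 2.5 m cells (200×200); depth ≈ 25–40 m from a linear
  trend plus six smooth bumps, clamped to 11–80 m.
* Habitat = **depth band × substrate patch**: two quantile depth bands
  crossed with two patch types from a thresholded smoothed Gaussian field.
  The angular-response model attaches to *substrate*, not to class: classes
  sharing a substrate across depth bands share an AR law. This is the
  physical statement that acoustics see the seabed material while depth
  structures the biology — so neither bathymetry nor backscatter alone
  determines class, and an informative classifier needs both.
* AR law: level = μ + slope·(θ − 40°) for θ ≥ 25°, plus a quadratic
  near-nadir rise below 25° (8 dB at nadir). Linearity over the 30–50° band
  is deliberate: feature-recovery oracles have closed forms. Substrate means
  are 6 dB apart (−18, −24 dB), slopes −0.05 and −0.15 dB/°.
* Noise: 5 dB per-sample Gaussian (speckle-scale for dB-domain intensity),
  and a 2 dB-sd constant gain offset per survey line. The line offsets
  emulate the residual along-track artefacts real mosaics retain after
  statistical compensation — a constant per-line term passes through the
  sliding-window normalization exactly, while per-segment AR curves pool
  lines and average it away. Without this term the synthetic mosaic is an
  unrealistically perfect substrate map and the angular-response features
  have nothing left to add.
* Survey: east–west lines 40 m apart, one ping per 2.5 m, 121 beams over
  ±60° (integer-degree steering), flat-seafloor footprints, unsigned angles.
* Ground truth: 150 cell-centre points per class, stratified 70/30.

What the synthetic world does **not** emulate: physical scattering models,
refraction, vessel motion, beam-footprint smearing, positioning error,
spatially correlated speckle, and ground-truth misclassification. A green
pipeline-recovery test therefore establishes that the *machinery* — from
per-beam samples to evaluated maps — preserves and exploits the angular
information as designed, not that any particular accuracy would be achieved
at sea.

## Numerical choices and degenerate inputs

* Angle bins are centred on multiples of the bin width (`round(θ/w)`), so
  integer-degree beams land exactly on bin centres and noiseless curves
  reproduce the generating law bin-exactly.
* 8-bit rounding is half-up (`floor(x + 0.5)`), documented because banker's
  rounding would shift single grey levels.
* Merging ties in segmentation (equal similarity) resolve to the lower
  region id; the small-region phase absorbs the smallest region first. Small
  regions isolated by nodata stay unmerged (segments never span nodata).
* Zero-variance curves: slope 0, skewness/kurtosis NA. Fewer than 5
  populated bins: the whole feature set is undefined and rasterises to
  nodata.
* Vote ties in prediction go to the lowest class id; forests are
  deterministic in (data, seed).
* An all-nodata mosaic segments to an empty set; a sample set entirely
  outside the template grids to an all-nodata mosaic with a warning.
* Kappa variance is undefined when chance agreement is 1 (single-class
  degenerate matrix); the Z test warns and returns NA when both variances
  vanish.

## Known limitations

* GeoTIFF support is a minimal single-band uncompressed codec (the target
  environment has no GDAL binding): enough for round-tripping this
  pipeline's products and reading plain uncompressed rasters, not arbitrary
  production GeoTIFFs. ESRI ASCII is the fully general text path; polygons
  are written as GeoJSON (no shapefile writer).
* The region-growing implementation follows the published description of the
  cited algorithm family, not the binary behaviour of any specific legacy
  software; absolute segment boundaries may differ from other tools at equal
  parameters.
* Importance-based selection inherits the known biases of impurity
  importance under correlated predictors; out-of-bag permutation importance
  is available via `train_rf(importance = "permutation")`, and the ranking
  should be read qualitatively either way.
* The Z test's independence assumption is inherited from the cited
  accuracy-assessment practice (see above).
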