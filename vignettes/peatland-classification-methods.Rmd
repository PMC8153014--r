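---
title: "Multi-source peatland classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-source peatland classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(peatstack)
```

`peatstack` classifies tropical peatland landscapes by fusing three
complementary observation types: optical reflectance (rich spectral detail,
blinded by cloud), radar backscatter (all-weather, sensitive to vegetation
structure and moisture), and elevation (wetlands align with valley bottoms).
This vignette documents the models the package implements, the parameters
that matter, and the choices made where the design was genuinely open.

## The processing model

### Cloud score and compositing

Optical time series are screened with a *mean-of-ramps* cloud score over
five cloud-sensitive layers: Blue, NIR, SWIR1 and the two detector proxy
layers (`Aerosol`, `Cirrus`). Each layer is rescaled linearly between a
documented clear anchor (score 0) and cloudy anchor (score 1) and the pixel
score is the mean of the five ramps, hence monotone in every input. The
default anchors are Blue and Aerosol (0.10, 0.30), Cirrus (0.02, 0.10),
NIR (0.50, 0.80) and SWIR1 (0.35, 0.70), chosen so that clear-sky land and
water stay near zero while optically thick cloud saturates at least the
blue/aerosol/cirrus ramps. The masking threshold defaults to 0.5.

The cloud-free composite is, per pixel and band, the **mean of the
observations between the 40th and 60th percentile values** of the valid
series. Percentiles use linear interpolation between order statistics (the
convention of `quantile(type = 7)`); the brute-force oracle in the test
suite pins this convention. Two degenerate situations needed decisions:

* with few observations the closed percentile interval can capture no
  observation; the composite then takes the single observation nearest the
  interval midpoint, equidistant ties resolving to the smaller value (this
  tie occurs systematically for two-observation series, whose interval
  midpoint is exactly their average);
* pixels with fewer valid observations than `min_valid` (default 1) are
  nodata.

The same operator composites the radar series, without any cloud mask,
since backscatter is weather-independent. The per-pixel-per-band reading of
the percentile range is the only one that yields a composite image and is
the one implemented.

Grids are aligned by nearest-neighbour resampling onto a 20 m analysis
grid: output aligned to the source origin, pixel-centre lookup, no
interpolation (categorical rasters can never acquire new categories). A
single CRS is assumed throughout; mismatched origins are an error, not a
silent warp.

### Features

Thirty-six candidate layers in six nested combinations — S2 (10 optical
bands), S2+ (plus 10 spectral indices and the NDVI texture), S1 (VV, VH),
S1+ (plus 6 GLCM statistics, 2 window-SD textures, 2 temporal amplitudes),
S2+S1+ (33) and S2+S1+DEM (36, adding elevation, slope, aspect).

* **Spectral indices** are computed pixel-wise from the reflectance
  composite. The red-edge position index uses the standard form
  `705 + 35·(((RE3 + Red)/2 − RE1)/(RE2 − RE1))`. Zero denominators and
  non-finite results become nodata rather than infinities.
* **Window standard deviation** is the population SD over a 5×5 window,
  nodata-aware, with reflection padding at the edges.
* **GLCM textures** quantise a layer to `Ng = 32` grey levels over its
  global valid range, accumulate a symmetric co-occurrence matrix over the
  four directions (0°, 45°, 90°, 135°, both senses) at offset distance 4,
  pooling pairs anchored within a 3×3 neighbourhood of each centre pixel,
  and evaluate contrast, correlation and variance. The number of grey
  levels is unstated in common tool chains; 32 balances sensitivity
  against sparse matrices at this window size, and the explicit-matrix
  oracle in the tests pins the full parameterisation. Correlation is
  defined as 0 where the marginal variance vanishes so feature stacks stay
  dense. The implementation accumulates pair moments with box filters,
  which is algebraically identical to building each pixel's matrix — the
  test oracle builds the matrices explicitly and checks agreement to 1e−12.
* **Temporal amplitude** is p90 − p10 of the valid backscatter series — a
  dynamic-range feature tracking soil-moisture variability.
* **Terrain** uses Horn's 3×3 weighted finite differences; slope in
  degrees, aspect in degrees clockwise from north of the downslope
  direction, flat cells flagged nodata.

### Selection and classification

Features are standardised to mean 0 and unit *population* variance, with
parameters estimated on the training pixels only and re-applied to full
rasters at prediction (the prediction population is unknown at training
time). Zero-variance columns are flagged and scaled by 1.

Recursive feature elimination drops one feature per iteration — the one
with the lowest overall Gini importance — and records the stratified 2-fold
cross-validated overall accuracy at every subset size down to one. One
feature per step gives the finest-grained curve; overall accuracy is the
headline metric of the workflow and therefore the CV score. The fold
assignment is drawn once per run (seeded, stratified by class) and held
fixed along the elimination path, so the curve reflects feature content
rather than fold noise. The optimum maximises the curve, ties breaking
toward the smaller subset (parsimony).

The classifier is a random forest with `ntree = 100` and `mtry = 2`
candidate features per split (`mtry` in its standard meaning). Prediction
is the majority vote over trees; any pixel with a missing feature is
nodata — no imputation. A single-pass 3×3 majority filter smooths the map;
ties for the modal class retain the centre pixel, so the filter never
invents a class and is idempotent wherever a strict majority exists.

Per-class feature importance is
`score(c, f) = overall_importance(f) · |mean standardised value of f over
training pixels of c|` — the class-conditional-mean reading, with the
absolute value keeping scores non-negative. The alternative reading
(feature values at split nodes) is not recoverable from a fitted ensemble
without retraversal and would depend on tree internals; the
class-conditional mean is stable, interpretable and testable.

### Evaluation

Confusion matrices tally reference classes by row and predictions by
column; UA is column-wise correctness, PA row-wise, OA the diagonal share.
The per-class F-score is the harmonic mean `2·UA·PA/(UA + PA)/100`. Map
pairs are compared by McNemar's test on discordant counts,
`χ² = (f12 − f21)²/(f12 + f21)` with one degree of freedom and no
continuity correction; discordant counts are tallied over shared test
points valid in both maps. Area accounting multiplies class pixel counts
by the pixel area (0.04 ha at 20 m) and aggregates general classes via the
catalogue; percentages are reported over the total mapped area and, for
wetland shares, over the land area excluding open water. Internal values
keep full precision; rounding to the reporting precision (2 dp for
F-scores and areas, 1 dp for UA/PA) happens only at the reporting layer.

## The synthetic-scene generator

The generator is first-class, tested code that defines the study
conditions for every downstream check. It emulates:

* a **coastal-plain DEM**: a monotone trend rising inland over 60 m,
  smooth-field roughness (sd 4 m), and three meandering valley lines
  carved a quarter of the relief deep;
* a **patchy class map**: per-class suitability = an elevation affinity
  (zero inside the class's preferred interval, decreasing outside) plus a
  smooth random field with a 12-pixel correlation length; each pixel takes
  the argmax. A deterministic multiplicative-weights calibration nudges
  per-class biases toward the configured target proportions (equal by
  default) so all twelve classes appear with workable prevalence while
  water and the peatland classes stay confined to valley bottoms;
* **optical series** (default 12 dates, 200×200 at 20 m): class mean
  reflectance per band plus a sinusoidal annual cycle and Gaussian noise,
  clipped to [0, 1], with spatially contiguous cloud fields covering the
  configured fraction (default 0.2) per date — cloudy pixels brightened in
  all bands and overwritten high in Blue/Aerosol/Cirrus;
* **radar series** (default 12 dates): class mean linear power times
  Gamma(looks, looks) multiplicative speckle (unit mean, the standard
  multi-look model; default 5 looks), stored in dB;
* **reference data**: rectangular training polygons fully inside
  single-class patches and stratified-random test points disjoint from
  them, labels copied from the truth.

The default class signatures are declared fixture values, not estimates of
any real landscape: they follow broad spectral expectations (water dark in
the infrared, vegetation with a strong NIR plateau and red-edge slope,
built-up/bare bright in visible and SWIR, smooth water dark in radar,
volume-scattering canopies bright in VH) and place classes on plausible
elevation intervals. What the passing tests therefore show is that the
pipeline recovers *structure it is designed to detect* — class
separability, noise-feature irrelevance, elevation dominance, the
radar-only accuracy penalty — not that it attains any particular accuracy
on real imagery: real scenes add mixed pixels, atmospheric residuals,
geolocation error, class spectral overlap and non-Gaussian textures that
the simulator deliberately omits (as do radiometric subtleties like SAR
geometric distortion).

## Problem sizes and numerical choices

The default experiment runs on a 200×200 scene (40,000 pixels, 4×4 km at
20 m) with 12 optical and 12 radar dates — ample for stable statistics
while keeping a full six-combination run in minutes on one CPU. Multi-seed
ordering properties use 80–100-pixel grids and five seeds. Percentile
interpolation is the linear order-statistic rule throughout; random-forest
fits are seeded and bit-reproducible; raster I/O stores 32-bit float
samples (band-wise affine rescaling with per-band validity pages), so
round trips are exact to float32 resolution.

## Known limitations

* The cloud score is a documented simplified detector, with per-band
  anchors as configuration; it is not a port of any production cloud
  algorithm.
* Rasters are in-memory matrices; scenes far beyond ~10⁷ pixels would need
  tiling, which is out of scope.
* Reference polygons are axis-aligned rectangles (what the generator
  emits and the GeoJSON reader reconstructs); arbitrary polygon rasterisation
  is not implemented.
* Accuracy magnitudes on synthetic scenes are a property of the declared
  signatures and should not be quoted as expected performance on real
  imagery.
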