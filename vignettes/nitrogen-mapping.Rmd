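---
title: "Mapping canopy nitrogen and folivore feeding habitat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping canopy nitrogen and folivore feeding habitat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitroscape)
```

## Scope and rationale

`nitroscape` estimates foliar total nitrogen (N, % of leaf dry matter)
of forest canopies from five-band multispectral reflectance and maps
favorable feeding habitat for *Eucalyptus*-specialist arboreal
folivores at the home-range scale (4 ha). The pipeline assumes inputs
of the kind a small UAV survey produces after photogrammetric
processing: a calibrated reflectance orthomosaic with blue, green,
red, red-edge and near-infrared bands (center wavelengths near
475/560/668/717/840 nm), a canopy height model (CHM), and a field
table of sampled trees with laboratory nitrogen measurements.
Photogrammetry itself (structure-from-motion, radiometric panel
calibration) is out of scope: the package starts from calibrated
rasters, and its synthetic-scene generator produces such rasters
directly.

## The models

### Tree-level nitrogen regression

Each sampled tree is summarized as the mean of 19 spectral variables
(5 bands + 14 indices) over up to 1000 randomly subsampled,
NDVI-masked crown pixels. Means of per-pixel index values are used
rather than indices of mean reflectance; the two differ for any
nonlinear index (Jensen's inequality), and the per-pixel order matches
how crown pixels are extracted in the first place.

The regression protocol is deliberately conservative about the small
sample a field campaign yields (~150 trees):

* **Correlation pruning.** Features are pruned until all pairwise
  Pearson |r| < 0.8. The greedy rule drops, from the worst pair, the
  member with the larger mean absolute correlation to everything else.
  Greedy pruning does not guarantee the minimum number of removals in
  general; the test suite checks it attains a minimal solution on a
  structured case.
* **Stratified 70/30 partitions.** The response is ranked into 5
  quantile bins and 70% of each bin trains the model, so both splits
  span the nitrogen range. On 150 trees this yields exactly 105/45.
* **Random forest** (`randomForest`), `mtry = ceiling(p/3)`, tree
  count chosen from {100, ..., 1000} by minimum out-of-bag MSE, with
  500 used when the curve is flat (relative spread < 1%).
* **Variable selection at 5% incMSE.** Importance is defined as the
  raw permutation increase in out-of-bag MSE expressed as a percent of
  the forest's out-of-bag MSE. The scaled "%IncMSE" some
  implementations report is a z-score and is not comparable to a 5%
  floor, so the raw ratio is used.
* **100-repeat evaluation.** "Cross-validation" is out-of-bag
  evaluation on the 70% training split; "independent validation" is
  prediction on the 30% held-out split. Out-of-bag evaluation is the
  natural forest analogue of k-fold cross-validation and requires no
  extra nesting; the two streams are reported separately throughout.
  Aggregates are mean, median, SD, SE = SD/sqrt(repeats), and CV.
* **Outlier rule.** Visual outlier screening is replaced by a
  reproducible rule: observations with |studentized residual| > 4
  from a preliminary linear fit are dropped. Four sigma keeps the rule
  inert on clean data and removes only gross laboratory or matching
  errors.

Digestible nitrogen (digN) runs through the identical machinery, but
no predictive floor is asserted for it anywhere in the package: in
field data its relationship to these five bands is explanatory at
best, and the package treats its modelling as exploratory.

### Pixel-level habitat classification

Pixels inherit their tree's class at the folivore feeding threshold:
favorable when tree N ≥ 1.0% DM (boundary inclusive), unfavorable
below. Classes are balanced by subsampling an equal count per class
(25,000 each at field scale) before a binomial random forest is fit on
a 70/30 split. The operating threshold is the score cutoff maximizing
TPR + TNR on held-out pixels (Youden's J); kappa at that threshold is
reported as a separate statistic rather than being used as the
selection criterion, since maximizing TPR + TNR is the operational
rule the skill panel is built around. The default split is
pixel-level; `group_by_tree = TRUE` keeps all pixels of a tree on one
side, because pixel-level splits leak tree identity between training
and validation — the option exists precisely so users can measure that
leakage.

### Home-range mapping

The classifier is applied to every pixel of a 4-ha crop; pixels below
the field-measured minimum subcanopy height are masked to non-habitat
(understory and ground were never sampled for foliage, so predictions
there are extrapolation); remaining pixels are classified at the
operating threshold. Summaries report the mean and SD of favorable
probability over canopy pixels only (the mask precedes the statistic),
while the favorable area fraction uses the full extent as denominator
(so fractions across the three classes sum to 100%). Aggregation is
measured by FRAGSTATS clumpiness under rook adjacency with double
counting and no background exclusion; the same 4-neighbor convention
is used by the watershed, keeping one adjacency rule package-wide. A
brute-force adjacency oracle in the tests pins this convention
exhaustively on small rasters. Bitterlich expansion
(10000 / (π c² d²), c = 25 for BAF 4) converts the tallied sample
trees to represented stems per hectare.

### Plot-level detection model

Plot survey tables average the five sampled trees' nitrogen per plot.
Glider observations are binarized to detection (count ≥ 1) — the
package models detection, not abundance — and a binomial GLM of
detection on mean plot N is fitted by IRLS to relative tolerance 1e-8.
Wald 95% intervals are the default; profile-likelihood intervals are
available behind `profile_ci = TRUE` (the two differ noticeably at
n = 30, and published interval endpoints for such fits are typically
profile-based, so both are offered while point estimates are the
primary output). Complete separation is detected (diverging estimates
or fitted probabilities at machine bounds) and flagged with a warning
rather than silently reported. Empirical detection thresholds — the
minima of mean N, mean favorable likelihood and favorable fraction
over detection plots, plus rates per elevation band and per nitrogen
bin — are computed from the table, never hard-coded.

## The synthetic-scene generator

The generator exists so every downstream stage can be tested against
known truth. What it emulates:

* a square scene (default 200 m = 4 ha) with survey plots spread over
  three elevation bands (lowlands / mid-hills / high elevation);
* a species pool whose mean nitrogen rises with elevation
  (defaults 0.95–1.55% DM, inside the observed field range of roughly
  0.6–1.9% DM), per-tree N drawn around the species mean (SD 0.15);
* five sampled dominant trees per plot plus background canopy trees;
* paraboloid crown domes — the simplest shape giving each tree a
  single height maximum, which is exactly what a local-maximum
  detector needs — with crown width linear in height
  (width = 1 + 0.16·height ± 0.25 m) so the allometry is recoverable;
* a documented linear reflectance-nitrogen link: green = 0.08 +
  0.05·N, NIR = 0.45 + 0.10·N, red-edge weakly increasing, blue and
  red flat; ground pixels get low-NDVI baselines. The link places the
  recoverable signal in the green band and green/NIR differences, the
  band combinations known to track nitrogen absorption;
* zero-mean Gaussian sensor noise per pixel and band (default SD
  0.01 reflectance), reflectance clipped to [0, 1];
* digestible N as total N times a per-species digestibility in
  [0.5, 1] (so digN ≤ N always), with a configurable fraction of
  trees missing digN, mirroring laboratory sample loss;
* per-plot detections drawn from the logistic detection model
  (default logit −5.6 + 3.6·meanN).

Within-crown nitrogen variance is exposed as `crown_n_sd` but defaults
to 0: field campaigns sample one branch per tree, so no empirical
value exists; at 0 the reflectance link inverts exactly, which the
recoverability tests exploit.

What it does **not** emulate — and what passing tests therefore do not
show about real data: shadows and within-crown illumination gradients,
species-specific spectra beyond the nitrogen link, sensor
vignetting/BRDF effects, co-registration error between CHM and
orthomosaic, crown overlap and understory green-up. Synthetic
performance (R² ≈ 0.9) is accordingly an upper bound; the protocol,
not the score, is what transfers.

Trees are placed on a jittered grid inside each plot with spacing
checked against the worst-case crown width, so crowns never overlap
and configurations that cannot fit are rejected up front
("overcrowded"). The default pixel size is 0.25 m rather than a UAV's
~2.5 cm: a 4-ha scene is then 640,000 pixels, which keeps desk-scale
runs fast, and resolution remains configurable.

## Numerical conventions

* **Rasters** are plain numeric matrices in a `band_stack` container
  (origin upper-left, row-major, cell centers at half-pixel offsets);
  file IO is 32-bit float TIFF with a JSON sidecar for pixel size,
  origin and layer names.
* **Division by zero** in any index yields `NA`, and `NA`-carrying
  pixels are dropped before modelling; VARI is undefined exactly where
  Green + Red − Blue = 0.
* **Local-maximum plateaus** (exact height ties in one window) are
  merged over the 8-neighborhood and the cell nearest the plateau
  centroid becomes the marker — deterministic and
  orientation-independent.
* **Watershed** is Meyer's priority flood seeded at markers,
  4-neighbor, FIFO on exact height ties; cells below the height floor
  stay unlabeled.
* **CHM resampling**: where a CHM grid differs from the feature grid,
  nearest-neighbor resampling is the intended convention (the
  synthetic scenes render both on one grid, so the package never
  interpolates heights).
* **Threshold ties** in the operating-threshold scan break toward the
  lowest threshold; candidate thresholds are the unique score values.
* **Seeds**: every stochastic function takes an explicit seed and
  restores the caller's RNG state; repeated evaluation uses
  `base_seed + repeat index`.

## Problem sizes used in the tests

The test suite builds a 140 m scene (4 plots, 52 trees, 560×560
pixels at 0.25 m) once and reuses it: nitrogen-model recovery is
checked over 20 repeated splits, the classifier on a 4,000-pixel
balanced set, the full-scene map against the generator's label truth,
and logistic parameter recovery over 100 replicates of 500 plots.
Exhaustive brute-force oracles run on rasters up to 8×8 and score sets
up to 50 points. The whole suite completes in well under a minute on
one CPU.

## Known limitations

* Manual crown correction is replaced by a polygon-override hook
  (`apply_crown_overrides()`); there is no interactive editing.
* Crown outlines are convex hulls of segment cells — metadata only;
  all computation uses the label raster.
* The package ships no georeferenced-format driver; TIFF + JSON
  sidecar stands in for GeoTIFF, and coordinates are scene-local
  meters.
* digN mapping is intentionally not offered: with these five bands the
  digN model lacks predictive power, and mapping it would present
  noise as signal.
* Pixel-level classifier validation shares trees between splits unless
  `group_by_tree = TRUE`; grouped validation is the honest but more
  pessimistic choice.
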