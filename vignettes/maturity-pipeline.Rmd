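---
title: "Predicting buckwheat maturity from plot-level RGB imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting buckwheat maturity from plot-level RGB imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(buckmat)
library(dplyr)
```

## The problem

Buckwheat ripens unevenly: grains at different maturity stages coexist on one
plant, and plants at different stages coexist in one plot. Harvesting early
loses immature grain; harvesting late loses shattered grain. The question this
package addresses is whether the *days remaining until harvest* of a plot can
be predicted from nothing more than an overhead RGB photograph of its canopy —
the kind of image a consumer-grade UAV produces — exploiting the fact that the
canopy's colour (green → flower-white → golden brown) and texture (crisp
sowing rows early, closed rough canopy late) change systematically through the
squaring, flowering, growth and maturity periods.

The pipeline is: segment canopy from soil, summarise each plot-date image as a
22-dimensional feature vector, attach a corrected days-to-maturity label,
prune redundant features, let recursive feature elimination with
cross-validation (RFECV) pick the feature subset per regression family, and
evaluate with a correlation-based R² and RMSE, plus permutation feature
importance (PFI).

Because the original field imagery is not publicly distributed, the package
ships a synthetic scene generator that reproduces the *statistical structure*
of such a campaign. Every stage is tested against that generator's known
ground truth.

## Segmentation

Plots are dense enough that single-plant segmentation is hopeless; the aim is
only to separate canopy from soil. The RGB image is converted to the excess
green index, ExG = 2g − r − b on channels scaled to 0–1, which is high for
green vegetation and low for soil. The ExG raster is split by two-cluster
1-D K-means and the higher-ExG cluster is labelled canopy; a morphological
opening then closing (disk, radius 2 px by default) removes speckle and fills
pinholes.

Numerical choices worth knowing:

* K-means is initialised at the 25th/75th ExG percentiles, which makes the
  binarisation deterministic; a constant raster (e.g. bare soil) is rejected
  with an explicit error rather than returning an arbitrary split.
* Channel scaling by 255 only fixes the reported scale of ExG; the
  binarisation is invariant to it.
* Morphology uses replicate border padding, so an all-canopy mask is a fixed
  point and re-applying the same radii changes nothing.
* The disk radius (2 px) is small relative to the default 256 px plots; it is
  a parameter, not a constant.

## The 22 features

Each plot-date image is summarised over its canopy pixels:

* **5 vegetation indices** — NGRDI = (g−r)/(g+r), GLA = (2g−r−b)/(2g+r+b),
  VARI = (g−r)/(g+r−b), ExG = 2g−r−b, NDYI = (g−b)/(g+b). All but ExG are
  scale-invariant ratios. Pixels whose denominator magnitude falls below
  1e−6 are excluded from that index's mean (VARI's denominator g+r−b can
  genuinely vanish); if every pixel is excluded the error names the index.
* **9 colour components** — the H, S, V of HSV; H, L, S of HLS; L, a, b of
  CIE Lab (sRGB primaries, D65 white). Hue is circular, so it is aggregated
  with a circular mean on [0, 1). HSV hue and HLS hue are the same formula;
  the package computes them through two independent code paths
  (`grDevices::rgb2hsv` vs. an explicit piecewise HLS conversion) and the
  test suite asserts their correlation is exactly 1 — a deliberate
  cross-check, and the reason one of the pair is always pruned later.
* **8 texture features** — six grey-level co-occurrence matrix statistics
  (homogeneity, contrast, dissimilarity, entropy, angular second moment,
  correlation) on the canopy-masked luminance quantized to 32 levels,
  distance 1, symmetric, averaged over the 0°/45°/90°/135° angles; the mean
  rotation-invariant uniform local binary pattern code (8 integer neighbours,
  radius 1); and the mean Gabor response magnitude (0.25 cycles/px, 4
  orientations, σ = 2 px, zero-DC kernels, replicate-padded convolution).
  GLCM pairs that straddle the mask are discarded, so soil never contaminates
  canopy texture. All texture parameters are exposed via `texture_params()`.

Texture is computed on canopy-masked pixels (not the full crop) for
consistency with the segmentation stage's purpose. GLCM correlation is
undefined for a constant texture; `glcm_stats()` flags it as `NA` and
`extract_features()` turns that into an error naming the feature rather than
silently imputing.

## Labels

The nominal label MD is the exact calendar-day difference between capture and
harvest; the six default capture offsets {36, 30, 24, 17, 7, 3} correspond to
a September–October campaign against a 15 October harvest. Because plots
ripen unevenly, MD is corrected by the canopy brown-pixel fraction *p*:
a plot browner than its date suggests matured earlier (fewer remaining days).
The correction is D = 1.5·(1 − 2p), a linear map onto the open interval
(−1.5, 1.5) days — a total window of three days around the nominal date —
and the corrected label is MMD = MD + D.

Two design points were genuinely open:

* *What counts as brown.* The brown detector is an HSV window (hue 20–50°,
  saturation ≥ 0.15, value 0.15–0.85 by default). There is no canonical
  definition of "brown canopy pixel"; the window is validated against the
  synthetic generator's own brown reference colour and is fully configurable
  for real imagery.
* *The shape and sign of the correction.* Only the range of D is fixed by the
  problem statement; the linear, centred, decreasing-in-*p* map is this
  package's choice. More brown ⇒ negative correction ⇒ earlier maturity.

## Feature selection

**Pruning.** Features whose pairwise |Pearson r| exceeds 0.9 are grouped
(connected components of the correlation graph) and each group keeps only the
member most correlated in absolute value with the label, ties going to the
earlier column. The retained set is data-driven — on a different campaign a
different set survives, which is why no feature list is hard-coded anywhere.

**RFECV.** Recursive feature elimination drops the single least-important
feature per refit (linear models rank by |standardized coefficient|, i.e.
|coef|·sd(x), because raw coefficients are incomparable across feature
scales; tree ensembles by impurity/gain importance), producing a nested
elimination path. The cross-validated variant runs the path on each training
fold only and scores every subset size on the held-out fold — selection never
sees the scoring rows — then picks the smallest size whose mean CV score is
within 1e−9 of the maximum (parsimony tie-break: past the plateau, more
features buy computation, not accuracy). The final subset is the full-data
RFE result at that size. Five folds is the default.

## Regression families and evaluation

Six families are supported behind one interface: decision tree (rpart),
linear (OLS), random forest, AdaBoost.R2 (Drucker's regression variant over
depth-3 rpart learners, authored in-package: weighted refits with linear
loss, weighted-median prediction), gradient boosting (xgboost, squared-error
objective, single-threaded for determinism), and extremely randomised trees
(ranger with the extratrees split rule, no resampling). Hyperparameters are
the libraries' defaults lightly pinned for reproducibility, all exposed via
`control`; every family is deterministic given its seed.

The package's R² is the **squared Pearson correlation** between estimates and
measurements. That definition is symmetric and shift/scale-invariant — a
uniformly biased predictor still scores 1 — so RMSE (in days) is always
reported beside it, and the conventional residual-based 1 − SSres/SStot is
available as `r_squared_ss()`. PFI is the drop in that R² when a single
feature column is shuffled, averaged over K = 10 shuffles by default; a
feature the model never consults has PFI exactly 0.

Because no single train/test protocol is canonical here, the evaluation grid
(`run_grid()`) reports k-fold CV, an 80/20 holdout, and training-set metrics
for every feature-space × family cell, each averaged over 5 repetitions with
distinct derived seeds.

## What the synthetic generator emulates — and what it does not

A campaign is `n_plots` × six capture dates (35 × 6 = 210 samples by
default). Per image, at 256 × 256 px:

* **Canopy cover** rises from 0.35 at 36 days to 0.85 at harvest (crops grow
  and close).
* **Canopy colour** drifts from vivid green (50, 110, 40) to a dull
  green-brown (90, 100, 55); an increasing fraction of canopy pixels
  (0 → 0.85, linear in maturity progress) is drawn from a golden-brown
  mature-grain distribution (150, 112, 35). Soil is (115, 75, 70). The brown
  reference sits inside the default brown-detection window and between soil
  and green in ExG — closer to green, so the 2-means split keeps mature
  canopy on the canopy side.
* **Row texture**: canopy placement probability carries a sinusoidal row
  modulation (period 16 px) whose amplitude fades linearly toward harvest,
  mirroring rows that are crisp at squaring and invisible at maturity.
* **Placement coherence**: canopy pixels are placed by thresholding a
  spatially correlated uniform field (rank-transformed smoothed Gaussian
  noise, correlation length 3 px). Each pixel is still marginally
  Bernoulli(p), but canopy forms leaf-scale blobs — independent per-pixel
  draws would be salt-and-pepper speckle that any morphological opening
  erases, which is not how canopies look. Brown assignment *within* the
  canopy stays independent Bernoulli per pixel; this is a stand-in for
  within-plot maturity heterogeneity, not a claim about buckwheat biology.
* **Noise**: additive per-channel Gaussian pixel noise (sd 6 of 255) and a
  per-image log-normal illumination factor (sd 0.05).

All randomness derives from a single integer seed (per-plot seeds are derived
deterministically), so identical configurations are bit-identical.

What it does **not** emulate: perspective and stitching artefacts, shadows
and specular highlights, weeds and lodging, mixed boundary pixels at real
optical resolution, spatially structured ripening gradients, or the
between-date weather variation of a real campaign. Consequently the synthetic
task is *easier* than any field campaign: the default simulation is predicted
with holdout R² near 1 and RMSE well under a day. Passing the test suite
demonstrates that the machinery is correct and that the pipeline recovers
known structure — not that it would reach any particular accuracy on real
imagery.

## Problem sizes used in the tests

Unit tests run on reduced scenes (48–128 px, 2–8 plots) where the property
under test does not depend on scale. The whole-method checks use the full
default campaign (35 plots × 6 dates at 256 × 256 px) for the end-to-end
recovery (majority over 5 seeds: holdout R² ≥ 0.9 and RMSE ≤ 3 days), and
500-row synthetic tables for pruning/selection recovery. These sizes are the
package's chosen study conditions, fixed before the assertions were frozen.

## Known limitations

* The brown-pixel window is tuned to the generator's colour world; real
  imagery will need its own calibration (and possibly a classifier rather
  than a box in HSV).
* Eq-style correlation R² rewards any monotone alignment; model comparisons
  should always read it together with RMSE.
* With only six distinct capture dates, the label is nearly discrete; models
  mostly interpolate between date clusters, and the within-date signal rests
  entirely on the brown-fraction correction (±1.5 days).
* `rfecv()` refits the model O(k · p) times; with slow families and wide
  tables the cost grows quickly (the 22-feature default is cheap).
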