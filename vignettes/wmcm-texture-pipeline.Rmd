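---
title: "Wavelet multi-sub-band co-occurrence texture features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet multi-sub-band co-occurrence texture features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`wmcmtex` implements a tile-level relapse-prediction pipeline for
histopathology images: blank-tile filtering, CLAHE contrast enhancement,
wavelet-domain co-occurrence texture features, SMOTE rebalancing, six base
classifiers and three ensemble combiners, with full evaluation tooling.
This vignette explains the model, its assumptions, the parameters that
matter, the synthetic data the package tests itself on, and the design
choices made where more than one reasonable convention exists.

## The model and its assumptions

The working assumption is that relapse-associated tissue differs from
unaffected tissue in its *second-order* gray-level statistics — how often
particular intensity pairs co-occur at a fixed spatial offset — and that
this signal is spread across spatial frequencies. The feature extractor
therefore:

1. decomposes each tile with one level of a separable orthonormal 2-D
   wavelet transform into four half-resolution sub-bands (LL
   approximation, LH/HL oriented details, HH diagonal detail);
2. quantizes each sub-band independently to $L = 16$ levels by min–max
   binning (detail coefficients are signed and band-dependent in scale,
   so a per-band mapping is the only one that uses the full level range
   in every band);
3. accumulates a directional gray-level co-occurrence matrix (GLCM) per
   sub-band at displacement $\nabla = 1$ along the diagonal, i.e. counts
   of pairs $\big(SB(a,b), SB(a{-}1,b{-}1)\big)$;
4. sums the four GLCMs element-wise into the wavelet multi-sub-band
   co-occurrence matrix (WMCM), whose normalized form is a probability
   distribution over level pairs pooled across frequency bands;
5. computes eleven statistics of the normalized matrix — two level-ratio
   dominance measures (`sgsda`, `sgbda`), the marginal means (`gla`,
   `dla`) and variances (`glmse`, `dlmse`), correlation, contrast,
   energy, entropy and homogeneity.

Both granularities are kept: the 11 aggregate WMCM statistics *and* the
11 statistics of each sub-band GLCM, 55 features per tile. The WMCM pools
texture across bands, but the per-band matrices retain orientation and
scale information that the sum discards; the classifiers consume all 55.
A weighted scalar texture score (weights non-negative, summing to one;
uniform $1/11$ by default, since no weighting scheme is privileged
a priori) is exported alongside for inspection and ranking, not used as
the sole classification input — a single scalar would discard most of the
discriminative signal the 55-dimensional vector carries.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `white_threshold` | 220 | Intensity (8-bit) at or above which a pixel counts as blank; near-white is the standard background criterion for H&E tiles. |
| `max_blank` | 0.30 | Tiles with blank ratio strictly above this are discarded; the boundary value itself is kept. |
| CLAHE `n_grid` | 8 | Contextual grid of 8×8 sub-tiles per image — 64×64-pixel sub-tiles on 512-pixel input. |
| CLAHE `clip_max` | 2 (standard mode) | Histogram counts clipped at `clip_max` × mean bin count, excess redistributed uniformly. |
| `wavelet` | `haar` | Orthonormal, energy-preserving, and free of boundary ringing on small tiles; `d4` available. |
| `levels` (L) | 16 | Co-occurrence level count; 16 keeps the 256-cell matrix well populated on 256×256 sub-bands. |
| `delta`, `orientations` | 1, `diagonal` | Single diagonal displacement; `"all"` sums the four standard directions. |
| `train_fraction` | 0.8 | Stratified 80:20 split. |
| `smote_k` | 5 | SMOTE neighbour count, capped at one less than the minority size. |
| `cv_folds` | 5 | Folds for the accuracy-proportional ensemble weights. |
| `threshold` | 0.5 | Probability decision threshold; ties classify positive. |

## CLAHE: two clipping conventions

Canonical CLAHE limits contrast by clipping the *histogram* at a multiple
of the mean bin count and redistributing the excess before forming the
CDF; the lookup table still ends at 255 and the output uses the full
range. An alternative convention clips the *CDF* itself into
$[0, \text{clip}_{\max}]$; for $\text{clip}_{\max} < 1$ this caps the
lookup table at $255\,\text{clip}_{\max}$ and darkens the output
globally. Both are implemented (`mode = "standard"` and
`mode = "paper_literal"`); the standard form is the default because it
limits noise amplification — the documented purpose of clipping — without
the global darkening artifact. Sub-tiles are non-overlapping and mapped
pixel-by-pixel through their own lookup table by default; bilinear
blending of neighbouring tables (`interpolate = TRUE`) is available for
users who prefer the seamless classic variant.

## Formula conventions in the statistics

Several of the eleven statistics admit more than one printed form in the
literature; the package fixes them as follows.

* `sgsda` $= \sum_{ij} p(i,j)/(i^2 j^2)$ and
  `sgbda` $= \sum_{ij} p(i,j)\, j^2/i^2$, by analogy with the
  small/large-dominance statistics of gray-gradient co-occurrence
  analysis; 1-based levels make every denominator positive.
* Homogeneity uses the squared-difference kernel $1/(1+(i-j)^2)$, which
  is symmetric, bounded in $(0, 1]$ and standard; a `"abs"` variant
  ($1/(1+|i-j|)$) is available. A signed form $1/(1+(i-j))$ would be
  singular or negative for $j > i$ and is not offered.
* Correlation is the standard GLCM correlation: cross-moment minus the
  product of marginal means, over the product of marginal standard
  deviations; it is defined as 0 when a marginal is degenerate.
* Entropy uses the natural logarithm with $0 \log 0 = 0$; the maximal
  value is $2 \log L$ at the uniform matrix.
* F-value is $2TP/(2TP + FP + FN)$ and MCC the standard Matthews
  coefficient. The consistency audit below confirms these are the forms
  under which every published row we bundle is internally consistent; a
  `literal` F variant with denominator $2TP + 2FN$ is kept for audit
  purposes only.

## Resampling order

SMOTE interpolates synthetic minority rows between nearest minority
neighbours (Euclidean distance on z-scored features; interpolation in the
original space, so synthetic rows lie componentwise between two real
rows). Two orderings are shipped because reasonable descriptions of such
pipelines disagree:

* **standard** (default): split first, oversample the training fold only.
  The test set then contains exclusively real samples and the reported
  performance is uncontaminated.
* **paper_literal**: oversample the full table, then split. Synthetic
  rows can land in the test set, which inflates apparent performance;
  published evaluations whose test sets contain "manufactured" samples
  follow this order, so it is provided for faithful reproduction, clearly
  not as the recommended practice.

## Ensembles

Weights for the weighted-averaging combiner are proportional to each
learner's out-of-fold accuracy under stratified cross-validation on the
training set — "performance-based" weighting without test-set leakage —
and normalized to sum to one. Soft voting is exactly weighted averaging
with uniform weights. Hard voting takes the majority of thresholded
labels; a 3–3 tie among six learners classifies positive, since in a
relapse-screening setting a missed positive is costlier than a false
alarm. For ROC analysis the hard-vote ranking score is the fraction of
positive votes (seven distinct values for six learners).

AdaBoost is implemented in-package (discrete boosting of depth-1 CART
stumps, $\alpha_t = \tfrac12\log\frac{1-\varepsilon_t}{\varepsilon_t}$,
probabilities through the logistic link of the additive margin) because
no boosting-of-stumps implementation is available among the package's
dependencies; SVM, logistic regression, CART, random forest and XGBoost
delegate to `e1071`, `stats::glm`, `rpart`, `randomForest` and `xgboost`.

## The synthetic texture generator

The generator produces the statistical structure the pipeline assumes —
a second-order texture difference between classes — and nothing else.
Negatives are fine texture (i.i.d. uniform noise, 3-pixel box smoothing);
positives are coarse texture (21-pixel smoothing plus a period-96,
amplitude-40 sinusoidal grating). Intensities are stretched to [10, 210]
so clean tiles never trip the blank filter, and an optional near-white
square patch fixture exercises it deliberately. The default dataset is 25
positive / 102 negative tiles of 512×512 pixels at seed 42 — the
imbalance shape of a small relapse cohort at desk scale, with 512-pixel
tiles so one decomposition level yields 256×256 sub-bands.

What it emulates: class imbalance, controllable second-order texture
separation (coarse tiles have non-overlappingly lower aggregate WMCM
contrast than fine tiles at 50 tiles per class), blank regions, 8-bit
quantization. What it does not: H&E colour chemistry, nuclei and stromal
morphology, stain variation, slide-level correlation between tiles, label
noise. The classes are separable *by construction*, so perfect held-out
accuracy on the fixture validates the plumbing and the features'
discriminative direction — it says nothing about attainable accuracy on
real histology, where class overlap, batch effects and weak labels
dominate.

## Numerical choices and degenerate inputs

* Wavelet filtering uses periodic boundary extension; orthonormal filter
  pairs then preserve energy exactly (asserted at 1e-6 relative
  tolerance). Odd-sized tiles are padded by edge replication first.
* A constant sub-band quantizes to level 1 everywhere; its GLCM puts all
  mass on one cell, where energy = homogeneity = 1 and
  entropy = contrast = correlation = 0 — all features stay finite.
* Ensemble and texture-score weight sums are validated to 1e-9.
* Metrics with zero denominators are reported as `NA` rather than
  silently zeroed; an empty confusion matrix is an error.
* Matching printed 2-decimal tables uses round-half-up (with a 1e-9
  guard against binary-representation artifacts), not banker's rounding.
* The stratified split takes `floor(train_fraction * n)` training rows,
  apportioned per class by floor-plus-largest-remainder with ties to the
  lower label; both splits always retain both classes.
* A single global seed fans out to fixed per-stage seeds (split, SMOTE,
  training, weights), so any stage can be re-run in isolation and full
  runs are bit-reproducible.

## The table-consistency audit

`infer_confusion_matrix()` enumerates every integer confusion matrix
with total ≤ 60 whose accuracy, precision, sensitivity and specificity
round half-up to a printed 2-decimal row. For all nine bundled reference
rows the solution is unique, implies 52 held-out samples, and reproduces
the printed F-value and MCC to 0.01 — which is what justifies the
standard-formula reading above. (The bundled cohort description states 51
test samples while every recovered matrix totals 52; the audit surfaces
this discrepancy rather than resolving it.)

## Problem sizes used by the test suite

Unit tests run on 32–128-pixel tiles and small grids; the co-occurrence
oracle comparison uses 200 random grids up to 8×8; the separability
assertion uses 50 tiles per class at 256 pixels; the end-to-end
determinism and accuracy checks run the full default fixture (127 tiles,
512 pixels) twice. These sizes were chosen so the whole suite exercises
every path at full default resolution at least once while staying quick
enough for routine development.

## Known limitations

* One decomposition level only; multi-level wavelet-packet trees are out
  of scope.
* Grayscale only — colour moments and stain-aware processing are not
  implemented; RGB input is collapsed by the luminance formula.
* The directional GLCM is not symmetrized by default (the counting
  definition is directional); use `orientations = "all"` for a more
  rotation-robust variant.
* The accuracy-proportional ensemble weighting is one defensible reading
  of "performance-based" weighting; exact reproduction of any particular
  published ensemble row from image data is not claimed, and the bundled
  published rows are used only as audit inputs.
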