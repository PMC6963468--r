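---
title: "Methods: block-statistical mammogram classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: block-statistical mammogram classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammocad)
library(dplyr)
```

`mammocad` classifies mediolateral-oblique (MLO) mammogram views as normal
or abnormal (mass lesion present). This vignette is the package's account of
the underlying procedure: the model at each stage, its assumptions, the
tunable parameters and why their defaults are what they are, what the
synthetic phantom generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## Segmentation model

An MLO view contains the breast, the pectoral muscle (a dense triangle
touching the top corner on the chest-wall side), and possibly radiopaque
labels disconnected from the tissue. Classification features must be
computed from breast tissue only, so segmentation proceeds in a fixed
order:

1. **Orientation.** The breast is mirrored to the left when the right half
   of the frame holds more foreground (intensity ≥ 18) pixels than the left
   half. A single chirality means one seed-placement rule serves all images.
2. **Artifact suppression.** Binarize at the global threshold 18 — the
   conventional cut separating film background from tissue on 8-bit
   mammograms — apply a morphological opening with a disk of radius
   `max(1, round(min(H, W)/200))`, and keep the largest 8-connected
   component. Labels are disconnected from the breast, so they vanish; the
   radius scales with image size so the opening removes thin bridges
   without eroding the breast outline at any resolution.
3. **Pectoral removal.** Seeded region growing (SRG) from the topmost, then
   leftmost breast pixel inside the top-left 25% × 25% window. A frontier
   pixel joins the region when its intensity differs from the *running
   regional mean* by at most `tolerance`; the frontier is processed FIFO
   with row-major neighbour enumeration, which makes the grown region a
   deterministic function of the image. The region is blacked out.

The SRG literature leaves the homogeneity criterion, seed placement, and
tolerance open; all three are parameters here. The default `tolerance = 32`
is about twice the phantom parenchyma standard deviation (16): large enough
to absorb pectoral texture, small enough that the pectoral–parenchyma
intensity gap (≈ 55 grey levels under the phantom defaults) blocks leakage.
If the grown region nevertheless exceeds half the breast area the growth
has escaped into parenchyma — the degenerate case where no pectoral
triangle exists. The region is then reported with a warning but the image
is left unmasked: blacking out half the breast would be strictly worse than
doing nothing, and the caller can inspect the returned mask.

## Enhancement

CLAHE follows the classic five steps: tile the image (default 8 × 8),
build 256-bin tile histograms, clip each at `clip × tile pixel count`
(default 0.01), redistribute the clipped excess, map through the cumulative
histogram, and interpolate each pixel bilinearly between the four
neighbouring tile mappings (clamped at borders). Redistribution is uniform
reallocation iterated until the residual is below one count, with the final
sub-one remainder assigned to the lowest bins — any mass-conserving
redistribution has the same fixed point, and this one is easy to verify:
the clipped histogram always sums exactly to the tile pixel count. With one
tile and `clip = 1` the procedure reduces to plain histogram equalization
under the mapping `m(v) = round(255 · cdf(v)/n)`, which the tests exploit
as an exact oracle.

## Feature model

Each image is partitioned into 16 × 16 blocks (partial edge blocks
discarded, so every formula sees exactly `F·G` pixels). Per block:
entropy in bits over the 256-level histogram, mean, *population* variance
(divisor `F·G`), standard deviation, range, minimum, maximum, and RMS.
Averaging each statistic over the `Z` blocks yields the 8-component image
feature vector in the canonical order (entropy, mean, variance, sd, range,
minimum, maximum, rms).

Three identities follow analytically and are asserted in the tests: the
mean feature equals the global image mean when blocks tile the image
exactly; image-level `range = maximum − minimum` by linearity of the block
average; and `sd ≤ sqrt(variance)` by Jensen's inequality. All eight
default features are invariant under quarter-turn rotations of a square
image, because rotation permutes blocks and rotates block contents, and
every per-block statistic is permutation-invariant in its pixels.

Two deliberate choices: entropy uses log base 2 with 256 levels (bits are
conventional, bounding the feature by 8); and RMS defaults to
`sqrt(mean(p²))` over block pixels — the reading that matches the name and
is rotation-invariant — while a directional row/column variant
(`rms_mode = "row_col"`, the arithmetic mean of squared row and column
means) is exposed for comparison. Blocks that are entirely background after
segmentation are included by default; there is no principled masking rule
that keeps `Z` consistent across images of different breast sizes, and the
all-zero blocks affect both classes identically.

## Classifiers and ensembles

All classifiers share one contract: fit on a data frame with numeric
feature columns and a binary `label` (abnormal = 1 = positive class, fixed
so the confusion-matrix metrics are unambiguous), predict classes or
probability rows that sum to 1.

- **k-NN** (default k = 2) computes Euclidean distances on features min–max
  scaled to [0, 1] using training-fold statistics only — unscaled, the
  variance feature (order 10²–10³) would dominate entropy (order 1).
  Even k needs a tie policy: the nearer neighbour decides, and an exact
  distance tie falls to class 0. Distance ties rank by training index.
- **Gain-ratio trees.** Greedy top-down binary splits on numeric
  thresholds (midpoints between consecutive distinct values) maximizing
  gain ratio; stop on purity, `min_leaf = 2`, a depth cap, or no positive
  information gain. The pruned variant applies reduced-error pruning
  against an internal stratified 25% holdout (the classical pessimistic
  pruning constant is not part of the contract; reduced-error pruning is a
  documented, testable substitute). The random-tree variant samples
  `ceiling(log2(d) + 1)` candidate features per node and never prunes.
- **Random forest**: 10 random trees on bootstrap resamples, probabilities
  averaged.
- **Bagging** (any base kind, 10 members) averages member probabilities
  over bootstrap resamples; **AdaBoost.M1** uses weight-proportional
  *resampling* (not reweighting) so that base learners without a weighted
  loss — k-NN included — boost identically; its score is the alpha-weighted
  vote margin normalized to [−1, 1] and squashed through the logistic,
  giving a continuous, rank-faithful score for ROC analysis. **Averaging
  fusion** is the unweighted mean of heterogeneous members' probability
  rows, ties to class 0.

## Wrapper feature selection

The objective of a subset is the stratified k-fold CV accuracy of the
chosen classifier on the column-restricted data. Folds are drawn once per
search from the seed and memoized per subset, so the objective is a pure
function of the subset within a search. Best-first search keeps an open
list ordered by objective, expands the best node into single-feature
additions and deletions (bidirectional), and stops after `stale_limit = 5`
consecutive expansions without a new global best; with an unlimited stale
limit on d ≤ 8 it provably scores all 255 nonempty subsets, which the
tests compare against brute-force enumeration. Random search draws
uniformly random subsets alternating with single-feature mutations of the
incumbent, deduplicated, for a budget of distinct evaluations. Equal
objectives prefer the smaller, then lexicographically first subset —
parsimony plus determinism.

## Evaluation

Metrics come from pooled confusion counts with abnormal as positive:
accuracy, sensitivity, specificity, precision, F1. Zero-denominator metrics
report 0 with an `undefined` flag instead of erroring, so a degenerate CV
fold cannot crash a pooled report. AUC is the midrank Mann–Whitney
statistic, exactly the all-pairs probability `P(s⁺ > s⁻) + ½P(tie)` and
invariant under monotone score transforms. Cross-validation is stratified
(each class shuffled under the seed and dealt round-robin; five folds give
the 80–20 split); both pooled and per-fold metrics are reported since
either convention appears in practice. Nested selection chooses a
hyperparameter per outer training split by inner-CV accuracy and evaluates
only on the outer test fold.

## The phantom generator

Every stage is validated on synthetic MLO phantoms with ground-truth masks:

- breast silhouette: a half-ellipse attached to one lateral edge (touching
  the top corner, as an MLO breast does), filled with clipped Gaussian
  parenchyma texture N(100, 16);
- pectoral muscle: a filled triangle at the top corner covering
  `pectoral_frac` (default 0.3) of the top edge, intensity N(155, 4) —
  within 15 grey levels of the dense-tissue intensity
  `breast_mean + 3·breast_sd = 148`, emulating the density similarity that
  makes pectoral removal necessary;
- background: N(8, 2) clipped below the global threshold 18;
- labels: bright (≥ 200) rectangles near the far edge, guaranteed
  disconnected from the breast;
- lesion (abnormal class): a disk of radius 15% of the image height at
  fractional position (0.52, 0.32), shifting intensity by `3·breast_sd`
  and texture sd by +10.

Cohorts jitter acquisition parameters per phantom (breast mean ±4, sd ±1,
pectoral fraction ±0.04, lesion centre ±0.03; the pectoral intensity rides
on the jittered dense-tissue intensity so the density-similarity invariant
holds for every member). The lesion size was chosen by a design pilot
before any downstream test existed: with a 12%-radius lesion the best
single feature separated jittered cohorts with AUC ≈ 0.97 — detectable but
marginal against the between-phantom jitter — while 15% put the cohorts in
the clearly separable regime (AUC ≈ 1) that a 3-sigma intensity shift is
meant to represent. The lesion centre sits where the worst-case jittered
pectoral triangle and the breast boundary both keep a scale-free margin
from the lesion disk, so generation succeeds for every seed.

What the phantoms do *not* emulate: X-ray physics, scatter, compression
deformation, anatomic ductal structure, spiculated or non-circular masses,
calcifications, and the 1024 × 1024 resolution of digitized film (the
default 256 × 256 keeps test runtimes in seconds; the geometry is
resolution-free). Passing tests therefore demonstrate the pipeline's
correctness and its sensitivity to block-statistic shifts, not clinical
performance on real mammograms.

## Problem sizes and determinism

The test suite and the acceptance script run phantom cohorts of up to
50 + 50 images at 96–256 px, 20-phantom segmentation batches, 50-phantom
SRG–flood-fill comparisons, 200-point classifier oracles, and the full
255-subset feature-selection enumeration — sizes at which every stochastic
check is exact and the whole suite completes in about a minute on one CPU.
Every stochastic operation takes an explicit integer seed; child seeds are
derived arithmetically (staying within 32-bit range), so any result in the
package is reproducible from a single seed.

## Known limitations

- The SRG homogeneity criterion uses the running mean; region shape can
  depend on growth order in images with strong gradients (the FIFO order
  makes it deterministic, not order-free).
- Reduced-error pruning spends 25% of the training data; on very small
  folds the pruned tree can underfit relative to an unpruned one.
- AdaBoost's logistic-of-margin probabilities are rank-faithful but not
  calibrated.
- The directional `row_col` RMS variant is provided for completeness but is
  not rotation-invariant; the default pixel RMS is used everywhere else.
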