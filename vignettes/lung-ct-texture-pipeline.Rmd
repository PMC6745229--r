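---
title: "Texture-based lung nodule classification with chaotic crow-search feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based lung nodule classification with chaotic crow-search feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungtexsel)
```

## The pipeline

`lungtexsel` implements a classical computer-aided-diagnosis chain for
chest CT slices:

1. **Preprocessing and lung-field segmentation** — adaptive median
   filtering against impulse noise, automatic mixture-model (Otsu-type)
   thresholding, binarization, morphological opening with a
   periodic-line structuring element, complement, and removal of
   border-connected structures.
2. **Texture description** — gray-level co-occurrence matrices (GLCM)
   at offsets `(2, 0)` and `(0, 2)`, summarized by the 13 classical
   Haralick statistics and averaged across the two offsets into a
   single 13-vector per image.
3. **Wrapper feature selection** — a chaotic-binary crow-search
   metaheuristic (CCSA) whose random draws are replaced by a sine
   chaotic map, scoring candidate subsets by cross-validated
   classifier accuracy plus a parsimony term.
4. **Classification** — a probabilistic neural network (PNN), i.e. a
   one-pass Bayes–Parzen classifier with Gaussian radial-basis
   kernels.
5. **Evaluation** — stratified 10-fold cross-validation with pooled
   confusion-matrix metrics (sensitivity, specificity, accuracy, PPV,
   NPV) and mean squared error on the 0/1 class encoding.

Because clinical CT archives cannot ship with a package, every stage
is exercised on seeded synthetic inputs: geometric chest phantoms with
ground-truth masks, and labelled feature tables with a planted
informative subset.

## The phantom generator

`phantom_spec()` describes a square slice: a bright elliptical thorax
disk (mean intensity 220) on a dark air background (40), two dark
axis-aligned lung-field ellipses (100), and optionally one bright
nodule (180) of one of four archetypes — well-circumscribed,
juxta-pleural, vascularized (disk plus 1-px Bresenham vessel
segments), and pleural-tail (disk joined to the pleura by a thin
tail). Additive Gaussian noise (default sd 4) and salt-and-pepper
impulse noise (a per-pixel corruption probability) complete the
image. The bright-wall / dark-lung contrast matches real CT, and it is
the regime the segmentation chain is built for: after binarization the
chest wall is foreground, the complement turns the lung fields into
interior components, and border clearing removes the surrounding air
ring. The intensity plateaus are deliberately well separated so the
mixture-model threshold has an unambiguous optimum; radii and ellipse
axes are free parameters since nodule sizes are not prescribed beyond
a lower bound in the source imagery conventions.

What the phantoms do *not* emulate: Hounsfield calibration, anatomical
texture inside the lung fields, partial-volume effects, or 3-D
structure. Passing tests on phantoms therefore demonstrate the
correctness and composition of the operators, not clinical
performance.

`feature_table_spec()` plants class signal directly in feature space:
balanced two-class Gaussian tables (default 100 samples per class, 13
columns) where only the columns in `informative_idx` (default six,
marking the positions of angular second moment, contrast, correlation,
variance, entropy and homogeneity in the canonical ordering) separate
the class means by `effect_size * noise_sigma` (default 3 standard
deviations — a strong, clearly recoverable signal). This emulates the
setting where a subset of the texture features is diagnostic and the
rest are noise.

## Numerical and design choices

**Adaptive median filter.** The classical two-stage variant: the
window grows from 3×3 to `max_window` (default 7) until its median is
not a window extremum; the centre pixel is then kept unless it is
itself a window extremum (an impulse), in which case the median is
substituted. Windows are clipped at the image border; a border pixel
that ties with its clipped window's extremum follows the median path.
Implemented in C++ since it is the only per-pixel/per-window loop in
the chain.

**Thresholding.** `mixture_threshold()` minimizes within-class
intensity variance by an exhaustive scan over the observed intensity
values (computed with cumulative sums; verified in tests against a
naive variance scan). Ties resolve to the smallest candidate, and
pixels equal to the threshold binarize to background — the reference
description only fixes the strict inequalities, and assigning ties to
background makes the rule deterministic.

**Periodic line.** The element has `2 * (L + 1)` members at
`k * direction`, `k = ±1 .. ±(L+1)`, default `L = 2` and direction
`(1, 1)` (the direction is not prescribed, so it is configurable). The
origin is not counted as a member but is included when the element is
applied. Opening runs erosion then dilation with the reflected
element, so anti-extensivity and idempotence hold exactly.

**Border clearing.** Geodesic reconstruction from border seeds,
8-connected by default (4-connectivity available). It can only remove
foreground.

**GLCM.** Equal-width quantization of the observed (masked) range into
8 levels, non-symmetric counting — defaults of the tooling ecosystem
the method descends from; both configurable. Pairs with either
endpoint outside the mask are skipped, making the texture
segmentation-aware. The 13 Haralick statistics use natural logarithms
with `0 log 0 = 0`; sum variance is centred on the sum average (the
widespread convention; the variant centred on sum entropy descends
from a misprint); correlation and the information measure of
correlation are defined as 0 for degenerate matrices whose marginal
spread or entropy vanishes. The two per-offset vectors are aggregated
by arithmetic mean so that the selector always works on 13 features.

**Sine chaotic map.** `p' = (c/4) sin(pi p)` with `c = 4` and
`p0 = 0.7`. The orbit 0.5 → 1 → 0 is absorbing, so values within
`1e-6` of the interval ends are re-seeded to 0.7 plus a small
deterministic jitter derived from the step index; the sequence is
therefore fully reproducible. One global sequence is consumed in
order, two draws (`C_j`, then `C_z`) per crow per iteration.

**Crow-search update.** Each crow follows a uniformly chosen crow
`z`; with probability `AwPr` (realized as `C_z <= AwPr`) the followed
crow notices and the follower repositions uniformly at random,
otherwise it steps `y + C_j * fl * (N_z - y)` toward the followed
memory and is clipped to the unit box. This is the standard
crow-search semantics of the awareness probability — low `AwPr` means
mostly exploitation, high `AwPr` pure random search — which the
parameter's name and the exploration/exploitation description require.
Memories update only on strict fitness improvement, so the best-memory
history is monotone non-increasing.

**Wrapper fitness.** `0.99 * (1 - cv_accuracy) + 0.01 * |subset| / D`,
with accuracy from an internal stratified 5-fold PNN (spread 0.1 on
z-scored features) whose folds are fixed once per run, making fitness
deterministic and cacheable. The weights are the convention of the
chaotic-CSA feature-selection literature. Positions binarize at 0.5,
and an all-zero mask is promoted to the singleton at its largest
component so fitness is always defined.

A consequence worth stating plainly: with a strong planted effect
(3 sd per informative column) any three informative features already
classify near-perfectly, so the parsimony term makes the *minimal*
perfect subset optimal. The selector then returns ~3 features with
high precision (they are almost always informative ones) rather than
all six — recall of a redundant informative set is bounded by the
fitness it optimizes, not by search quality.

**PNN.** Bias `b = sqrt(-ln 0.5) / spread`, so a stored pattern at
distance `spread` activates at 0.5 — the convention of the toolbox
architecture the network mirrors. Features are z-scored with training
statistics by default (distance kernels need comparable scales), and
class scores are summed activations, which equals the equal-prior
Bayes rule under balanced classes. Predictions at small spreads use a
per-query shift of squared distances before exponentiation; the shift
rescales all class scores identically, preserving the argmax while
avoiding underflow, and makes the spread → 0 limit (1-nearest-
neighbour) numerically exact. Ties resolve to the lowest class index.

**Evaluation.** Stratified folds, pooled (micro-averaged) confusion
for headline metrics, per-fold reports alongside. Feature selection
defaults to per-fold (re-run on each training portion, never seeing
the held-out labels); a global mode reproduces the one-shot design in
which selection precedes cross-validation. Zero-denominator metrics
are reported as `NA`, never 0. MSE compares predicted hard labels to
the 0/1 encoding of the positive class.

**Seeds.** Every generator and the full pipeline take one integer
seed; child seeds derive from it by a fixed affine map modulo
`2^31 - 1`, and RNG state is always restored afterwards, so results
are bit-reproducible and independent of the caller's random stream.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(n_per_class = 60, image_size = 160, seed = 1)
run <- run_pipeline(cfg)
print(run)
```

The run simulates 120 phantoms, segments them (mean Dice against the
generator's lung masks is reported), extracts the 13 texture features
over the segmented masks, and evaluates the PNN with and without
crow-search selection, printing the five diagnostic metrics for both
arms and the accuracy improvement. Default problem sizes (60 phantoms
per class at 160 px; selection experiments at 100 samples per class
over 10 replicate seeds) were chosen so a complete run remains a
few-minute desk computation while keeping fold sizes meaningful.

## Limitations

- Phantom texture is homogeneous inside compartments, so the GLCM
  features mostly reflect geometry and noise; phantom-cohort accuracy
  is a smoke signal, not a clinical estimate.
- The segmented lung mask excludes bright nodule pixels (they binarize
  with the chest wall), so masked texture sees nodules indirectly
  through mask geometry.
- Only single-slice 2-D processing; no nodule localization — the
  pipeline classifies whole images.
- The crow-search selector optimizes accuracy-with-parsimony; it is
  not a feature-recovery method when informative features are
  redundant (see above).
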