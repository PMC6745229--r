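# lungtexsel

Texture-based classification of lung CT slices with chaotic crow-search
feature selection and a probabilistic neural network.

## What this package does

Computer-aided diagnosis of lung nodules from CT commonly follows a
classical chain: clean the slice, segment the lung fields, describe
their texture, select the informative features, classify. `lungtexsel`
implements that chain end to end, for researchers who want a tested,
reproducible reference implementation of each stage:

- **Segmentation** — adaptive median filtering (impulse-noise removal),
  automatic thresholding by minimizing intra-class intensity variance
  (the mixture-model/Otsu criterion), binarization, morphological
  opening with a periodic-line structuring element (`2·(L+1)` members,
  default `L = 2`), complement, and clearing of border-connected
  structures.
- **Texture** — gray-level co-occurrence matrices at offsets `(2, 0)`
  and `(0, 2)` and the 13 classical Haralick statistics
  (angular second moment, contrast, correlation, variance, inverse
  difference moment, sum average, sum variance, sum entropy, entropy,
  difference variance, difference entropy, information measure of
  correlation, homogeneity), averaged across offsets into one
  13-vector per image.
- **Feature selection** — a chaotic-binary crow-search algorithm
  (CCSA): `M = 25` crows hold positions `y ∈ [0,1]^D`; each follows a
  random crow `z`, stepping `y ← y + C_j · fl · (N_z − y)` toward the
  followed crow's memorized best `N_z` (flight length `fl = 2`) unless
  an awareness draw `C_z ≤ AwPr = 0.1` triggers a uniform random jump.
  The draws `C_j, C_z` come from the sine chaotic map
  `p' = (c/4)·sin(π p)` (`c = 4`, `p₀ = 0.7`) instead of a uniform
  RNG. Positions binarize at 0.5 into feature masks, scored by the
  wrapper fitness `0.99·(1 − cv-accuracy) + 0.01·|subset|/D`.
- **Classification** — a probabilistic neural network (Bayes–Parzen
  classifier): training stores the patterns verbatim; the radial-basis
  layer computes `aᵢ = radbas(‖wᵢ − p‖·bᵢ)` with `radbas(n) = e^{−n²}`
  and `b = √(−ln 0.5)/σ`; the competitive layer returns the class with
  the largest summed activation.
- **Evaluation** — stratified 10-fold cross-validation, pooled
  confusion-matrix metrics (sensitivity, specificity, accuracy, PPV,
  NPV) and MSE `(1/N)Σ(Tᵢ − Oᵢ)²` on the 0/1 class encoding.

Clinical archives cannot ship with a package, so every stage is
exercised on seeded synthetic inputs: chest phantoms with two
lung-field ellipses, four nodule archetypes (well-circumscribed,
juxta-pleural, vascularized, pleural-tail) and ground-truth masks; and
labelled feature tables with a planted informative subset (by default
6 signal-carrying columns out of 13).

## Worked example

```r
library(lungtexsel)

cfg <- pipeline_config(n_per_class = 10, image_size = 96, k = 5,
                       ccsa = ccsa_config(M = 5, t_max = 4),
                       selection_mode = "global", seed = 2)
run <- run_pipeline(cfg)
print(run)
```

```
pipeline run (seed 2, config 22735dd226e22520641135ae35215e7b)
  10 phantoms/class, mean segmentation Dice 0.999
  all 13 features:      Sens 70  Spec 80  Accu 75  PPV 77.78  NPV 72.73  (%)
  CCSA-reduced features:Sens 70  Spec 90  Accu 80  PPV 87.5  NPV 75  (%)
  accuracy improvement: 5.00 points
```

The run simulates 20 phantoms (nodule-bearing vs. nodule-free),
segments each slice (mean Dice is the overlap with the generator's
ground-truth lung masks — here 0.999), extracts the 13 texture
features over the segmented masks, and cross-validates the PNN twice:
with all features and with a crow-search-selected subset. The five
percentages are pooled over the folds; at this deliberately tiny demo
size each fold holds only four test slices, so the improvement row
fluctuates from seed to seed. A single selection run on a planted
feature table looks like:

```r
tab <- generate_feature_table(feature_table_spec(seed = 1))   # 100/class, 6 informative
sel <- select_features(tab$X, tab$labels, ccsa_config(), seed = 1)
print(sel)
```

```
CCSA selection: 4 of 13 features, best fitness 0.0031, cv accuracy 1.000
selected: contrast, variance, entropy, difference_variance
```

With a strong planted effect (3 sd on each informative column) a few
informative features already separate the classes perfectly, so the
parsimony term of the fitness makes the selector return a *minimal*
perfectly-discriminating subset — here 4 features, 3 of them from the
planted informative set — rather than the full redundant set.

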