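---
title: "Methods: deep OCT features, ant-colony feature selection, and the benchmark harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep OCT features, ant-colony feature selection, and the benchmark harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the models and
update rules, the tunable parameters and their defaults, the synthetic data
the tests rely on, the numerical choices, and the known limitations.

## 1. The pipeline

`octaco` classifies retinal OCT B-scans into five disease classes (ARMD,
BRVO, CRVO, CSCR, DME). The pipeline has four stages, each persisting a
file artifact so stages are independently testable and resumable:

dataset scan + stratified split → deep feature extraction → ACO feature
selection → classifier benchmark.

## 2. Dataset manifests and the 80:20 split

`scan_dataset()` walks a `root/<class>/<image>` tree (png/jpg/jpeg/tif,
case-insensitive; anything else is skipped with a warning) and records each
image in lexicographic path order. `split_manifest()` assigns per-class
test counts as `round_half_up(test_fraction * class_total)` — commercial
rounding, not R's round-half-even. This is the only simple rule that
reproduces all five reference per-class tallies exactly (e.g. 738 → 148
test / 590 train, 313 → 63/250 at 20 %). Which images land in the test set
is uniform at random under the split seed; the source data carries no usable
acquisition order, so a seeded random stratified draw is the defensible
default.

## 3. Modified backbones and the linear-probe transfer regime

`build_modified_backbone()` instantiates ResNet-50, DenseNet-201 or
InceptionV3 as an explicit layer graph at a fixed 224×224×3 input, removes
the original 1000-class head, and attaches a new five-class fully connected
head fed by the global-average-pool (GAP) activation. The pooled widths
are the architectural ones — 2048 (ResNet-50), 1920 (DenseNet-201), 2048
(InceptionV3). Note that in transfer-learning practice 1920 is the
DenseNet-201 pooled width; descriptions that attribute 1920 to InceptionV3
conflate the two, and this package always reports the true architectural
width.

Forward passes run through the package's own im2col + GEMM kernels
(Rcpp/Armadillo). Batch-norm layers are carried in inference form
(per-channel affine); convolution weights are He-initialized from a seeded
RNG. ImageNet-pretrained weights are not bundled: `pretrained = TRUE`
requires a user-supplied weights file (`backbone_weights()` defines the
format), and every shape/ordering contract in the package holds for
randomly initialized bodies, so the test suite never depends on weight
downloads.

**Design choice — frozen body.** `finetune()` implements transfer learning
in the linear-probe regime: the convolutional body stays frozen, GAP
features of the training split are computed once and standardized, and the
new head is trained by minibatch SGD on softmax cross-entropy (defaults:
100 epochs, minibatch 64, learning rate 1e-4; a 1e-5 variant is used by
some DenseNet-201 training schedules and can be configured). Full
backpropagation through 50–201-layer bodies is deliberately out of scope:
with a frozen body the head converges in seconds on desk-scale data, the
loss history remains one entry per epoch, a zero learning rate is exactly
a null update, and training is bit-reproducible under the config seed.
The cost of this choice is that body features are not adapted to OCT
statistics; with random-initialized bodies, the exported features are a
fixed nonlinear projection, which is sufficient for every structural
contract and for above-chance classification of the stylized fixtures, but
is not a claim about clinical-grade accuracy.

Preprocessing is minimal and fixed: grayscale read (RGB averaged), bilinear
resize to 224×224, replication to three channels, ImageNet mean/sd
standardization. No denoising, registration or augmentation.

## 4. The ACO feature selector

The selector operates on an N×d feature table with labels. Its state is a
pheromone vector δ (length d, initialized at δ₀) and a visibility vector v.

**Visibility.** The default heuristic (`heuristic_mode = "fisher"`) scores
each feature by a Fisher class-separability ratio: the population variance
of the class means divided by the mean within-class population variance.
Constant features score 0; perfectly separating features (zero
within-class variance, separated means) receive twice the finite maximum
of the others. A `paper_literal` mode sets v equal to the pheromone vector
instead — a degenerate heuristic retained for fidelity experiments; it
makes the transition rule pheromone-only and is not the default precisely
because a heuristic identical to the pheromone cannot guide selection.

**Transition rule.** An ant builds a subset of `subset_size` features
sequentially, without replacement. At each step, with probability `q0`
(default 0.3) it exploits: argmax over remaining features of
δ_j^α · v_j^β (ties to the lowest index). Otherwise it samples feature j
with probability proportional to δ_j^α · v_j^β over the remaining
features (α = β = 1 by default). If all remaining products are zero the
draw is uniform.

**Fitness.** The quality of a subset is the held-out accuracy of a
1-nearest-neighbor classifier on the subset's columns, under a seeded
stratified 70/30 split fixed once per run (so all subsets are scored on
the same partition) with train-statistics standardization. This is cheap,
parameter-free, and deliberately *not* one of the downstream benchmark
classifiers, to avoid selection bias toward the final evaluation. Fitness
values are memoised per subset within a run.

**Updates.** Per iteration, every ant of the colony constructs and scores
a subset; the iteration-best subset receives the local deposit
δ_j ← (1−μ)·δ_j + μ·fitness (μ default 0.1) on its member features, then
the global evaporation δ_j ← (1−θ)·δ_j + θ·δ₀ (θ default 0.05) pulls every
feature toward δ₀. Both updates are convex combinations of positive
quantities, so pheromone positivity is invariant; the evaporation has δ₀
as an exact fixed point and contracts the sup-norm distance to δ₀ by
(1−θ) per application. An elitist best-so-far subset is tracked across
iterations, making the per-iteration best-fitness trace non-decreasing.

**Colony sizing.** The literal sizing rule Kn = V×d (samples × feature
width) is retained as a formal cap, but is astronomically large for deep
feature tables (500 × 1920 would be nearly a million ants); the default
`n_ants = "auto"` uses min(V×d, 32). `subset_size` defaults to half the
feature dimension, capped at 512.

**Pruning.** After the final iteration, `floor(prune_fraction × |subset|)`
features (default fraction 0.20; the admissible range is 15–20 % unless
explicitly overridden) are removed from the elitist subset by greedy
maximum-redundancy-first elimination: repeatedly drop the feature with the
highest maximum absolute Pearson correlation to the remaining kept
features, ties broken by lower visibility, then lower index. Pruning is
applied to the selected subset (not the full vector) — the natural reading
of removing "redundant features in the selected vectors".

**Symbols without a home.** The source formulation names a direction set
Δ = {0, π/4, π/2, 3π/4, π} and a quantity u_ef; both belong to pixel-grid
ant walks and have no feature-space meaning, so neither is used. The
transition expression is realized as the canonical pheromone-visibility
product rule, which is the standard form with exactly the named
ingredients (pheromone, visibility, an exponent).

## 5. Benchmark harness

`crossval_evaluate()` scores up to seven classifier presets on one shared
seeded stratified partition (ten folds by default; a holdout mode scores
the 20 % split instead). Features are standardized per fold with
training-fold statistics only — SVMs and KNNs on raw deep features are
scale-sensitive. Metrics come from pooled out-of-fold predictions:
accuracy, macro precision and recall from the pooled confusion matrix,
macro one-vs-rest AUC (each class against the rest on its score column,
averaged), and wall time per preset.

Preset hyperparameters are frozen in the registry and follow the defaults
of the classifier menu the preset names come from: polynomial-kernel SVMs
of degree 1/2/3 with box constraint 1 and coef0 = 1 (one-vs-one
multiclass); cosine KNN with k = 10; weighted KNN with k = 10 and
squared-inverse distance weights; random-subspace ensembles of 30
learners (1-NN or linear discriminant base) on ceiling(d/2)-dimensional
subspaces. "Subspace decrement" is accepted as an alias of the subspace
discriminant, matching a recurring typo for that preset name. SVM and LDA
learners are delegated to `e1071` and `MASS`; the two KNN variants and the
subspace ensembles are implemented in-package because no installed package
exposes cosine-metric or distance-weighted KNN with per-class vote scores.

## 6. Synthetic data

`make_planted_table()` draws, per informative feature, one mean per class
from N(0, class_sep²), then adds unit-variance noise; noise features are
iid standard normal; columns are randomly permuted and the informative
positions returned. `class_sep` is therefore an effect size in
within-class-sd units: at the default class_sep = 2 the expected
between-class spread is large enough that planted features dominate the
Fisher ranking in ≥95 % of seeds, while individual features can still be
weak by chance — as in real deep-feature tables. Default geometry is 5
classes × 100 samples, 10 informative + 90 noise.

`make_synthetic_oct()` writes stylized grayscale B-scans: a bright
horizontal retinal band over a speckled background plus one lesion
archetype per class (drusen-like bumps for ARMD, hemi-lateral band
thickening for BRVO, diffuse thickening for CRVO, a dark sub-band serous
dome for CSCR, intraretinal cystic blobs for DME). Per-image height is
sampled from 300–350 px and width from 1000–1050 px, emulating the source
acquisition geometry; class counts default to the reference distribution
scaled down 20× (37/22/16/37/38). These are texture caricatures that
exercise I/O, training loops and shape contracts; passing tests on them
demonstrates pipeline correctness, not clinical discrimination ability —
they contain no speckle physics, vessel shadows, or device artifacts.

## 7. Numerical choices and problem sizes

* Rounding in split arithmetic: round-half-up (`floor(x + 0.5)`).
* All randomness flows from explicit integer seeds; one pipeline seed
  derives per-stage seeds through a fixed affine map, so stages are
  reproducible in isolation. Ties break to the lowest feature index after
  the stated criteria, everywhere.
* Feature tables serialize with `%.17g`, so the disk round trip is
  bit-exact.
* 1-NN fitness and the KNN presets use squared-Euclidean distance via the
  Gram-matrix identity; distances clipped at 0 to absorb rounding.
* Transition probabilities normalize to 1 within 1e-12 and are exactly
  zero on excluded indices.
* Zero-variance columns standardize with sd set to 1; constant-column
  correlations are treated as 0 in pruning.
* The test suite and the acceptance script run at deliberately modest
  problem sizes — 20-image fixture trees for the image path, d ≤ 100
  tables for selection (10 seeds × 100 iterations × 32 ants), 200–500
  samples for the benchmark — chosen so the full suite completes in a few
  minutes on one core while still exercising every contract at the
  reference iteration counts.

## 8. Known limitations

* **Search optimality is heuristic.** With the product transition rule on
  raw Fisher ratios, selection probabilities can span orders of magnitude;
  on weak-signal instances whose exhaustive 1-NN optimum is partly a
  holdout-noise artifact (a lucky noise feature), the guided search may
  not reach that optimum within a small budget. Oracle-equivalence is
  therefore verified in the clearly separated planted regime, where the
  optimum is signal-determined; on noisy landscapes the selector should be
  read as a good-subset finder, not an exact optimizer.
* **Local deposits do not amplify pheromone above δ₀.** Since fitness ≤ 1
  and δ₀ defaults to 1, the local rule moves member pheromone *toward*
  the fitness value; with δ₀ = 1 exploitation pressure comes mostly from
  visibility. Setting δ₀ below typical fitness values (e.g. 0.5) makes
  deposits amplifying if stronger pheromone feedback is wanted.
* **No full-network fine-tuning**, as discussed in §3.
* The synthetic OCT renderer is stylized (§6); accuracy numbers on it do
  not transfer to clinical data.
* The benchmark's wall-time column measures this implementation on the
  host at hand and is reported for relative comparison only.
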