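---
title: "Instance-optimized multi-instance learning for texture-based lesion recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instance-optimized multi-instance learning for texture-based lesion recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

`iomil` classifies grayscale abdominal-CT-like images into a lesion class
(liver cancer) and a non-malignant class (normal parenchyma, cirrhosis, or
cyst) under *weak supervision*: labels are attached to whole images, never
to regions. The multi-instance learning (MIL) framing treats each image as
a **bag** and each equal-size square block tiled from it as an
**instance**; a bag is positive iff at least one of its instances contains
lesion tissue. This sidesteps tumor segmentation entirely — blocks are cut
on a fixed grid, so the method only needs a roughly cropped organ image.

The pipeline is:

1. **Preprocessing** — resize to a square frame (default 339 × 339 px,
   bilinear) and 256-bin global histogram equalization.
2. **Instance extraction** — tile into a `k × k` grid with
   `k = round(side / block_length)` and boundaries `round(i · side / k)`,
   so any block length, including fractional ones such as 169.5, yields
   disjoint tiles that cover every pixel, with tile sides differing by at
   most one pixel. Default block length 113 gives 9 instances per 339-px
   frame.
3. **Texture features** — for each block, gray-level co-occurrence
   matrices (GLCMs) at distances d ∈ {1, 2} and directions
   θ ∈ {0°, 45°, 90°, 135°}, accumulated symmetrically and normalized.
   From each table: angular second moment (ASM = Σ I²), entropy
   (ENT = −Σ I log I), contrast (CON = Σ (i−j)² I) and correlation
   (COR, with the standard GLCM marginal means/SDs). The feature vector is
   the mean and population variance of each statistic across the four
   directions, per distance: 16 values.
4. **First instance optimization** — a block consisting of a single gray
   level has ASM exactly 1 on every table; such uniform background blocks
   are discarded (`asm_mean_d1 ≥ 1 − tol`, default tol `1e-9`).
5. **Second instance optimization** — bags are dealt into folds (all
   instances of a bag stay together); each fold's instances are scored by
   an RBF SVM trained on the other folds, with every instance carrying its
   bag's label. Bags whose per-bag instance accuracy reaches a quantile
   cutoff contribute their *correctly classified* instances to the **key
   instance set**, the deployable training set. Positive-bag members get
   the flag `a_j = 1`, negative-bag members `a_j = 0`.
6. **CPSO tuning** — the SVM penalty `C` and RBF factor `g` are tuned by
   global-best particle swarm optimization in `log2` space, then refined by
   a coordinate line search (sweep `C` at fixed `g`, keep the best, then
   sweep `g`), both using the same stratified CV accuracy as fitness. The
   refinement can only keep or improve the swarm's fitness.
7. **Bag prediction** — instances surviving the background rule are
   predicted by the final SVM; with `r` the fraction predicted negative,
   the bag is negative iff `r > P` (strict), default `P = 0.86`.

Evaluation follows a five-group protocol: a stratified 50/50 train/test
split per class, the classifier built on the training half, the test half
dealt into five class-stratified groups, and ACC/SEN/SPE (overall
accuracy, lesion recall, non-malignant recall) averaged unweighted over
the groups. Ratios with empty denominators are reported as `NA`, never 0.

## Parameters that matter

| parameter | default | meaning / why |
|---|---|---|
| `block_length` | 113 px | tile side at the 339-px frame; 3 × 3 grid balances per-block statistics against mixing lesion and parenchyma in one tile |
| `P` | 0.86 | strict negative-ratio threshold, valid range [0.5, 1]; below 0.5 a bag with a minority of positive votes would be called positive |
| `levels` (G) | 64 | equal-width gray bins on [0, 255]; a standard compromise between gray-level resolution and sparse-count noise for ~113² blocks |
| `entropy_base` | 10 | log base for ENT; affects only the scale of one feature, which the tuned kernel absorbs |
| `asm_tolerance` | 1e-9 | numerical slack for the ASM = 1 background test |
| `excellent_bag_quantile` | 0.5 | per-class accuracy quantile for "high-accuracy" bags (see below) |
| `selection_folds` | 5 | bag-level CV folds in the scoring pass |
| PSO | swarm 20, 50 iterations, inertia 0.9→0.4, c1 = c2 = 2, box C ∈ [2⁻², 2⁷], g ∈ [2⁻⁴, 2⁴] | standard global-best PSO practice; all exposed in `pso_config()` |
| line search | steps 0.05, half-widths 1.0 (C) and 3.5 (g) | `lo_config()`; ties break toward smaller C (less overfitting) and smaller g (smoother kernel) |

## Design choices where the design was open

**Per-class accuracy quantile.** "High-accuracy bags" is made precise as a
quantile cutoff, computed *within each bag class*. When instance selection
works as intended, positive bags necessarily score low — most tiles of a
lesion image are not lesion tiles, so most of their inherited labels are
wrong — while negative bags score near 1. A pooled cutoff would then
discard every positive bag and leave a one-class (degenerate) training
set; the per-class quantile keeps the best-scored bags of both classes.

**The `a_j` flag.** The classifier-construction step assigns `a_j = 1` to
positive-bag key instances and `a_j = 0` to negative-bag ones, yet both
are added to the training set. The package treats membership in the key
set (not `a_j`) as what defines the training rows, because an SVM trained
without negatives is degenerate; `a_j` is kept as recorded metadata. The
alternative reading — the objective's slack mask, where `a_j = 0` rows have
their slack unpenalized — is available as `io_config(strict_aj_mask =
TRUE)`, realized as a small class weight on the negative rows.

**Scoring without self-training.** The scoring pass uses bag-level
cross-validation rather than train-and-score-on-self: self-scoring marks
nearly every instance "correct" and voids the selection.

**Background handling.** Background blocks are dropped at training time
and excluded from the prediction ratio's denominator; a test bag whose
blocks are all background raises a prediction error naming the bag rather
than guessing.

**Tiling rule for fractional lengths.** `k = round(side/length)` with
rounded equal partitions guarantees full coverage for any length; instance
order is fixed row-major for reproducibility.

**COR marginals and entropy base.** The source formulation of the
correlation marginals is dimensionally inconsistent (its `u_x` is
identically 1); the standard GLCM marginal definitions are used. Entropy
defaults to base-10 logarithms, configurable.

**Decision-value orientation.** libsvm orients decision values toward the
class it sees first in the training data; `decision_values()` normalizes
the orientation so a positive value always means the positive class, and a
decision value of exactly zero maps to +1 (documented tie rule). Feature
standardization inside `train_svm()` can be disabled (`scale = FALSE`) when
features are already on a common scale; note that with standardization,
duplicating training rows is *not* exactly solution-preserving (the n−1
sample SD changes and the total slack weight doubles).

## What the phantom generator emulates — and what it does not

`generate_phantom()` produces 512 × 512 8-bit frames: an elliptical
"organ" (≈45% of the frame, mild shape/position jitter) carrying
correlated Gaussian texture — white noise convolved with a Gaussian kernel
of width `texture_correlation_length`, scaled to `base_std` around
`base_mean` — on an exactly-zero background, so background tiles have a
single gray level and ASM exactly 1. Class signatures:

* **normal** — parenchyma texture only (`base_std` 12, correlation length 3);
* **cancer** — 1–3 irregular hypodense focal lesions (each a union of 3–7
  jittered disks, radius 20–45 px, contrast −45, internal SD 18),
  recorded in the ground-truth mask; the only positive class;
* **cirrhosis** — globally rougher parenchyma (`base_std` 28, correlation
  length 1.2), no focal lesion;
* **cyst** — one round, sharply bounded, internally homogeneous lesion
  (radius 25–50 px, contrast −60, internal SD 1).

Every phantom is a deterministic function of its configuration and seed,
and is passed through the same preprocessing as real data.

The generator is deliberately minimal: no Hounsfield-unit physics, no
anatomy, no partial-volume or scanner noise, no 3-D context. Passing tests
on phantoms shows the *mechanics* are right — tiling, features, selection,
tuning, thresholding — not that the method reaches any particular accuracy
on clinical CT.

One interaction is worth knowing about when interpreting phantom results:
global histogram equalization couples the tiles of a bag. A large dark
lesion shifts the whole image's histogram map, so even non-lesion tiles of
a lesion image differ measurably from normal-image tiles. This helps bag
classification but blurs the distinction between lesion and parenchyma
tiles inside positive bags; the test that checks lesion tiles are enriched
among the key instances therefore runs the pipeline without equalization,
isolating the per-tile selection mechanism.

## Problem sizes and numerical choices in the shipped tests

The test-suite experiments are desk-scale by design: the end-to-end
five-group check uses 80 cancer / 120 normal phantoms (the reference
dataset layout) with a reduced swarm (8 particles, 10 iterations, 3-fold
fitness) and a coarsened line search (step 0.25); the key-instance
enrichment check pools 10 seeds of 12 cancer / 16 normal phantoms, sized
for adequate binomial power; unit fixtures use 10–24 bags. High-contrast
phantom settings (lesion contrast −70, internal SD 25) are used where
clear class separation is the stated precondition. The GLCM oracle
comparisons run at 1e-12; swarm and fold dealing are fully seeded, and
every report records the resolved configuration.

## Known limitations

* Binary bags only; the multi-class extension is out of scope.
* One CPSO run per classifier (a per-fold option exists in the scoring
  pass); the swarm fitness is instance-level CV accuracy, not bag-level.
* The minimum Hausdorff bag distance used by the Citation-kNN baseline is
  not a metric (triangle inequality can fail); the WEMISVM-style baseline
  is a single-model mean-decision-value variant, not the full ensemble.
* Histogram equalization is applied to the whole frame, including
  background, and is not idempotent on quantized data.
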