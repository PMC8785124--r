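---
title: "Unified Focal losses for class-imbalanced segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unified Focal losses for class-imbalanced segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unifocal)
```

## The problem

Semantic segmentation of medical images is dominated by class imbalance.
*Input imbalance* is the raw prevalence of the structures: a colorectal
polyp covers roughly 9% of a frame, an enhancing brain tumour about 0.2%
of a volume. *Output imbalance* is the asymmetry of the errors a trained
model makes — with a vanishing foreground, per-pixel losses happily predict
background everywhere, producing high-precision, low-recall segmentations.
The choice of loss function is the main lever against both.

Two families dominate. Distribution-based losses (cross entropy and its
focal variants) are averages of per-pixel penalties on the predicted
probability of the true class, `p_t`. Region-based losses (Dice, Tversky)
penalise `1 -` an overlap score built from probability-weighted ("soft")
confusion counts. Compound losses mix one of each. This package implements
the complete hierarchy and its generalisation, the Unified Focal loss, with
analytic gradients, so that every member can both be analysed numerically
and actually drive training.

## The loss hierarchy

All losses operate on arrays of shape `(batch, spatial..., class)` with a
softmax class axis last and background as class 0; binary problems are
two-channel maps, so every definition is written once for general C.

* **Cross entropy**: mean over pixels of `-log p_t`.
* **Focal**: `alpha_t (1 - p_t)^gamma (-log p_t)` — the modulating factor
  suppresses well-classified pixels (conventional `alpha = 0.25`,
  `gamma = 2`).
* **Soft Dice** per class: `(2 tp + eps) / (2 tp + fp + fn + eps)`;
  Dice loss sums `1 - DSC` over the class set.
* **Tversky**: replaces the symmetric `fp`/`fn` weighting with `alpha fp +
  beta fn` (conventionally 0.3 / 0.7), trading precision for recall.
* **Focal Tversky**: `(1 - TI)^(1/gamma)` with `gamma = 4/3` — contrary to
  the Focal loss this *enhances* hard classes, keeping gradient signal
  alive as `TI` approaches 1.
* **Combo**: `alpha * mCE - (1 - alpha) * DSC`, with a beta-weighted cross
  entropy; note the subtracted similarity makes the loss negative at good
  solutions, bounded below by `-(1 - alpha)`.
* **Hybrid Focal**: `lambda * Focal + (1 - lambda) * Focal Tversky`, six
  hyperparameters in total.
* **Unified Focal**: groups them into three — `lambda` (component mix),
  `delta` (output-imbalance weight) and a single focal `gamma`. The
  symmetric variant applies the focal factors to every class; the
  asymmetric variant restricts *suppression* to non-rare classes on the
  cross entropy side and *enhancement* to rare classes on the Tversky
  side.

Every earlier loss is a special case of the Unified Focal loss.
`verify_reductions()` checks each stated edge numerically on seeded random
batches:

```{r}
rep <- verify_reductions(trials = 25, seed = 17)
glance(rep)
```

## Conventions this package had to decide

**Focal exponents.** The two printed component definitions of the Unified
Focal loss are inconsistent with the stated special cases: a modulating
exponent of `1 - gamma` on the cross entropy side cannot reduce to cross
entropy at `gamma = 0`. We therefore use exponent `gamma` on the cross
entropy side (suppression grows with `gamma`, `gamma = 0` recovers the
`delta`-weighted cross entropy) and `1 - gamma` on the Tversky side
(enhancement grows with `gamma`, `gamma = 0` recovers the Tversky loss) —
the only convention under which the reduction hierarchy closes. The
literal printed forms remain available behind `literal_exponents = TRUE`.

**Where `delta` sits in the modified Tversky index.** We follow the
printed definition: `mTI = (tp + eps) / (tp + delta * fp + (1 - delta) *
fn + eps)`, which the worked value `mTI = 0.3125` at `delta = 0.6` (for
counts tp = 2, fp = 6, fn = 2) pins down. Users should be aware that some
public implementations put `delta` on the false negatives instead; under
the convention here, raising `delta` *lowers* the loss of an FN-heavy
prediction on the rare class. The recall advantage of the asymmetric
Unified Focal loss in practice comes primarily from the unsuppressed,
`delta`-weighted rare-class cross entropy term.

**The cross entropy recovery carries a factor `delta = 0.5`.** Setting
`lambda = 1, gamma = 0, delta = 0.5` yields `0.5 *` cross entropy, not
cross entropy itself: the `delta` class weight never disappears. We verify
the identity at that scale rather than "fixing" it.

**Aggregation.** Distribution losses average over pixels within an image
and then over the batch. Region scores are computed per image — never
pooled across the batch — so batch size does not change loss semantics,
and are summed over all C classes by default (`class_set = "foreground"`
restricts to classes 1..C-1, since published binary experiments are
ambiguous on this point).

**Numerical safety.** Probabilities are clipped to
`[epsilon, 1 - epsilon]` (`epsilon = 1e-6`) before any logarithm, and the
same `epsilon` is added to numerator and denominator of every ratio score.
Clipping also keeps region-loss gradients finite: an unclipped perfect
prediction would put `(1 - TI)^(q - 1)` at `0^(negative)`. Hard
binarization is argmax over the class axis with ties broken toward the
lower class index. In `loss_gradient()` the gradient passes through
clipping as zero outside the clip range, and the base of fractional powers
is floored at `1e-12` so degenerate parameter corners (`delta` exactly 0
or 1 with a perfectly covered class) cannot emit infinities.

## The synthetic task generator

`generate_task()` emulates the prevalence regimes of the standard
class-imbalanced benchmarks (see `imbalance_presets()`: 9.3%, 8.7%, 4.8%,
0.2% foreground, and a nested 10.8%/0.2% two-foreground variant) without
any download. Soft-edged elliptical blobs define a smooth radial field;
thresholding that field at the per-image quantile matching the target
fraction gives exact prevalence control while keeping irregular,
boundary-ambiguous edges — the regime where losses actually differ.
Images are the mask plus class-dependent contrast (default 0.5) and
Gaussian noise (default sd 0.2), clamped to `[0, 1]`, mirroring intensity
normalisation without emulating scanner physics.

What the generator does *not* reproduce: anatomical shape priors, texture,
multi-modal channels, annotation noise, or inter-image correlation. A loss
ranking on these tasks therefore demonstrates the mechanics of imbalance
handling, not expected clinical performance.

```{r, fig.width = 6, fig.height = 3}
task <- generate_task(4, shape = c(64, 64), target_fraction = 0.05, seed = 1)
task
autoplot(task)
```

## The benchmark harness

The harness trains a deliberately tiny fully-convolutional encoder-decoder
(3x3 conv, mean-pool, 3x3 conv, nearest upsample, skip concatenation, 1x1
conv to softmax; ~1.3k parameters) by SGD with momentum 0.9, initial
learning rate 0.1, batch size 8, halving the rate after 3 stale validation
epochs and stopping after 6, keeping the best-validation parameters. The
claims under test are about losses, not architecture; the model only needs
to be differentiable, fast on one CPU, and able to fit the synthetic
tasks. Backpropagation is hand-written in R (im2col + matrix multiply;
the input gradient of a convolution is computed as a convolution with the
flipped, channel-transposed kernel) and is verified against finite
differences in the test suite.

Problem sizes were fixed once for desk scale: 200 images of 64x64 at 1%
foreground for the directional benchmark (train/val/test 128/32/40,
25-epoch budget), and 60 images of 48x48 at 5% foreground
(contrast 0.7, noise sd 0.1) with a 15-epoch budget for the `gamma`
stability sweep. Stochastic claims are formulated over seed
ensembles — e.g. the asymmetric Unified Focal loss is compared with cross
entropy on rare-class recall as a win rate across 10 training seeds, never
on a single run. With 1% foreground, batch-8 gradient noise is what lets
training escape the all-background plateau; cross entropy typically stays
on it, which is precisely the failure mode the Unified Focal loss was
designed to correct.

```{r, eval = FALSE}
task <- generate_task(200, shape = c(64, 64), target_fraction = 0.01,
                      seed = 101)
splits <- split_task(task, seed = 101)
res <- run_benchmark(
  list(ce = seg_loss("cross_entropy"),
       uf = seg_loss("unified_focal", variant = "asymmetric")),
  splits, seeds = 1:10, epochs = 25)
glance(res)
```

`loss_landscape()` exports the per-pixel / per-class loss terms as curves
over `p_t` and the modified Tversky index (the classic focal-modulation
picture), and `gamma_sweep()` re-trains over a `gamma` grid to check the
single remaining hyperparameter is stable. Because the exact curve
parameterisation of the published figure is not stated, the landscape
labels each exported component curve explicitly rather than claiming an
exact replication.

## Limitations

* The tiny model and synthetic tasks are a mechanism demonstration;
  absolute metric values are not comparable to U-Net results on real
  datasets.
* The Combo loss's multiclass `beta` weighting (all rare classes vs
  background) extends the published binary definition; it reduces to it
  exactly at C = 2.
* 3D tasks are generated and evaluated, but the bundled segmenter is 2D;
  training-based comparisons are 2D only.
* Confidence intervals on per-image metrics are left to the user (the
  report keeps raw per-image values), since the interval method used in
  published tables is unstated.
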