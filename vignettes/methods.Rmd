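---
title: "Block-based aneurysm segmentation with a one-two-one FCN: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-based aneurysm segmentation with a one-two-one FCN: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otoseg)
```

## The problem

Intracranial aneurysms are focal bulges of cerebral artery walls.  On
time-of-flight MR angiography (TOF-MRA) they appear as small bright saccular
structures attached to bright tubular vessels, embedded in a large, noisy,
mostly empty volume.  Automated segmentation of the aneurysm sac is hard for
two structural reasons this package is organized around:

* **Scale.** A clinical volume (e.g. 512 x 512 x 128 voxels) does not fit an
  accelerator, so it must be processed in fixed-size 3D blocks and the
  block-wise predictions re-assembled.
* **Imbalance.** The lesion occupies well under 0.1% of the voxels, so naive
  voxel-wise objectives are dominated by the background and most training
  blocks contain no lesion at all.

`otoseg` implements the full pipeline: block partitioning with
*disequilibrium culling*, a one-two-one encoder-decoder fully convolutional
network, loss ensembles (Dice + cross-entropy, Dice + boundary), surface
distance evaluation metrics, and a synthetic phantom generator so everything
is testable end to end without clinical data.

## Preprocessing: blocks and culling

`partition()` cuts a volume into blocks of a fixed shape (default
64 x 128 x 128 in (Z, Y, X) order) on a regular origin grid.  Two regimes
are supported:

* *Non-overlapping* (stride = block shape): an exact tiling when the
  dimensions divide evenly; used at inference so each voxel is predicted
  once.  A 128 x 512 x 512 volume yields 2 x 4 x 4 = 32 blocks.
* *Overlapping* (default stride = half the block shape): used for training,
  so any interior structure appears away from a block border in at least one
  block.  The overlap stride is a free parameter; half the block shape is
  the package default because it achieves that guarantee with the smallest
  block multiplication.

For dimensions the stride does not divide, the final origin per axis is
clamped to `dim - block`: blocks never pad, at the cost of extra overlap in
the last row.  `reassemble()` averages all block predictions covering a
voxel, which reproduces the source exactly on a tiling and is
order-independent on overlaps.

`cull_empty()` then discards every training block pair whose label block
contains no foreground.  On realistic geometry this removes the large
majority of blocks (the package's acceptance checks require > 75% discarded
on default phantoms) and is the first, blunt instrument against class
imbalance.  Culling is applied to training data only; inference must cover
the whole volume.

## The one-two-one network

`oto_net()` builds a cascade of three complete encoder-decoder structures of
depths one, two, and one.  All convolutions are 3 x 3 x 3 in SAME mode with
ReLU activations; downsampling is a stride-2 convolution that doubles the
channel count, upsampling a stride-2 transposed convolution that halves it.
Two connection types are deliberately distinct:

* *residual addition* inside a stage (the stage input is added element-wise
  to the output of its convolution run), and
* *stacked skip connections* across resolutions (the same-resolution encoder
  features are concatenated channel-wise onto the decoder features; the
  first decoder convolution then reduces the doubled channel count back to
  the level's nominal width).

With the default base width of 16 the channel schedule is 16 at full
resolution, 32 at half, 64 at the quarter-resolution bottleneck of the
middle structure.  The output head is a single-channel convolution with a
sigmoid, so the network maps a (Z, Y, X, 1) block to per-voxel foreground
probabilities of the same spatial shape.  The network is fully
convolutional: any input with spatial dimensions divisible by 4 (two
downsamplings) works, which is what makes CPU-scale testing at
32 x 64 x 64 or smaller meaningful.

```{r}
net <- oto_net(oto_model_config(base_channels = 16))
shape_trace(net, c(64, 128, 128))
```

### Numerical choices

The engine (C++ via Rcpp) implements the forward pass, exact adjoint-based
transposed convolutions, and analytic backpropagation, verified in the test
suite against finite differences through the whole graph.  Choices that were
genuinely open:

* **Initialization.**  Fan-in (He) normal initialization, seeded from the
  config.  Because the architecture carries no normalization layers, the
  closing convolution of every residual branch is initialized at zero with
  a small positive bias (0.01): each stage starts as the identity around its
  resampling path (the SkipInit idea), without which the 29-convolution
  cascade is not reliably trainable from scratch, and the small bias keeps
  the following ReLU gate open so those weights still receive gradient.
  The head bias starts at the logit of a low foreground prior (-2.2, about
  p = 0.1) rather than at 0: with half the probability mass on the
  background the first optimizer steps suppress the prediction globally and
  saturate the sigmoid before any foreground discrimination forms.
* **Dropout** (rate 0.5 by default) is
  placed after the deepest stage of each of the three structures, active in
  training only, so it cannot destroy shallow skip information.  For
  severely reduced widths (base 2-4 channels) dropout should be disabled:
  removing half of an 8-channel bottleneck is catastrophic, and the
  CPU-scale runs in this package do so.
* **Striding.**  Down/upsampling stride is 2 along all three axes; the
  symmetric decoder then restores the input shape exactly, which is the only
  reading consistent with a schedule that halves 128 to 64 to 32 in-plane
  and returns.
* **Dimension checks** happen before any computation: indivisible inputs are
  rejected with an explicit error rather than silently cropped.

## Loss ensembles

All losses are voxel means, so ensemble weights are scale-free across block
shapes.  For probabilities `p` and binary labels `g`:

* **Dice loss** `1 - (2*sum(p*g) + w) / (sum(p^2) + sum(g^2) + w)` with
  smoothing `w = 1e-5` guarding the empty/empty case.  Its complement is the
  Dice similarity coefficient: `dsc() + dice_loss() = 1` at vanishing `w`.
* **Cross-entropy**: the two-class expansion
  `-[g log p + (1-g) log(1-p)]`, clipped at `1e-7` so saturated predictions
  stay finite.  A literal foreground-only variant (`-g log p` alone) is
  available behind `foreground_only = TRUE`; it is degenerate for a sigmoid
  output (minimized by predicting 1 everywhere), which is why the two-class
  form is the default.
* **Boundary loss**: `mean(phi_G * p)` where `phi_G` is the signed Euclidean
  distance map of the label (negative inside, positive outside; exact
  voxel-centre distances via a separable lower-envelope transform).  It may
  be negative; it penalizes predicted mass in proportion to its distance
  from the true boundary.  Masks containing a single class have no boundary
  and yield `phi = 0`, so the term vanishes instead of inventing a
  convention.  `phi` is computed in voxel units by default
  (`phi_physical = TRUE` switches to mm); training-time geometry need not be
  metric, while the evaluation metrics always are.

`loss_config()` composes the ensemble: `dice`, `dice+ce`, or
`dice+boundary`, with auxiliary weight `lambda` (default 1).  Because the
raw boundary magnitude grows with block size, its gradient can dominate the
Dice term before the network has found any foreground at all, collapsing the
prediction to empty; `ramp_epochs` therefore scales `lambda` linearly from 0
to its full value over the first epochs.  The ramp is the recommended way to
run `dice+boundary` at small step counts, and mirrors how boundary losses
are scheduled in practice.

## Training and inference

`oto_train()` is the package's fitting function: min-max normalize each
volume (at training time, never at I/O time), partition overlapping, cull,
then Adam (learning rate 0.001 and batch size 2 by default, the settings
intended for the full-width network) over the surviving
blocks, with the signed distance map of each label block computed once and
cached.  The optimizer choice itself was open; Adam is the ubiquitous
default.  The returned `oto_fit` records per-step and per-epoch loss
components; `rss_of_loss_curve()` summarises a curve's volatility as the
residual sum of squares about its least-squares line (lower = more stable
optimization).

`predict()` on a fit partitions non-overlapping (no culling), forward-passes
every block, and averages overlapping predictions where present;
`evaluate_segmentation()` binarizes at 0.5 (the symmetric default) and
reports DSC, average surface distance, HD95, and
foreground-recall accuracy.  Surfaces are foreground voxels with a
6-connected background neighbour, volume faces counting as background;
directed Hausdorff distances use the linearly interpolated 95th percentile
of per-point nearest-neighbour distances.  Note the reported "accuracy" is
|P∩G|/|G| — a recall: a prediction covering everything scores 1 — so it is
only meaningful alongside DSC and the surface distances.

## The synthetic phantom

`generate_case()` emulates the statistical structure the method assumes:
bright random-walk capsule-chain vessels, a handful of spherical lesions
(3-7 mm, the clinically common detectable size class) attached to vessel
wall points, additive Gaussian noise, and a label marking *only* the lesion
voxels — vessels are background, because the segmentation target is the
aneurysm, not the vasculature.  Default geometry: 128 x 256 x 256 voxels at
(0.8, 0.5, 0.5) mm spacing, 6 vessels of radius 1-2.5 mm, 3 lesions,
intensities background 20 / vessel 150 / lesion 220, noise sigma 15.  These
defaults keep the lesion fraction below 0.1%, which is the imbalance regime
that motivates culling and the loss ensembles.

What the phantom deliberately does **not** emulate: Rician noise statistics,
flow artifacts, skull and brain parenchyma, anatomy, and — most importantly —
realistic lesion contrast.  Real TOF-MRA aneurysms are essentially
isointense with their parent vessel; the phantom gives lesions slightly
higher intensity so that a severely reduced network can identify them within
a CPU-scale training budget.  Passing tests on phantoms therefore
demonstrate that the pipeline's mechanics (blocking, culling, optimization,
reassembly, metrics) work and that the network can learn a volumetric
discrimination task end to end; they say nothing about clinical
segmentation accuracy, which requires real data and full-scale training.

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on one CPU, so they
use reduced configurations chosen once: phantoms of 32 x 64 x 64 to
64 x 128 x 128 voxels, networks of base width 2-4, blocks of 16 x 32 x 32 to
32 x 64 x 64, and at most 10 training epochs.  The learning check trains a
base-4 network on three high-contrast 64 x 128 x 128 phantoms (vessels
dimmed to intensity 60 against lesions at 220, noise sigma 8, so the
discrimination is decidable within the step budget) with 32 x 64 x 64
overlapping blocks under the Dice + boundary ensemble (lambda ramped over
90 epochs, so within the 10-epoch budget the boundary term acts as a light
late-stage regularizer; learning rate 0.003 with gradient averaging over
batches of 4 blocks, which stabilizes the reduced network where
single-block updates oscillate; dropout off) and requires
held-out DSC above 0.5 — far below clinical performance, but an order of
magnitude above the all-empty and random baselines it is compared against,
i.e. genuine learning.

## Known limitations

* The literal printed form of some equations required interpretation: the
  cross-entropy as printed carries only the foreground term (degenerate for
  a sigmoid head), and the boundary-loss derivation contains typographical
  artifacts; the implementation follows the standard formulations and keeps
  the literal variant available where meaningful.
* The "accuracy" metric is a pure recall by its printed definition; do not
  read it as voxel accuracy.
* `hd(A, B, quantile)` with `quantile < 1` is not symmetric under swapping
  masks with very different surface sizes; the max of the two directed
  percentiles is taken, which is the common convention.
* Training at full width (base 16, 64 x 128 x 128 blocks) is supported by
  the code but takes GPU-scale time; the package's engine is CPU-only by
  design.
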