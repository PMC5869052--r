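---
title: "Patch-based volumetric segmentation pipelines: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based volumetric segmentation pipelines: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(voxpipe)
```

voxpipe implements the machinery that surrounds a convolutional network in 3D
medical image analysis: data loading with spatial metadata, normalization,
augmentation, window sampling, whole-volume aggregation, losses, evaluation
metrics and a reproducible driver. This vignette is the package's own account
of the models it implements, the parameters that matter, the numerical choices
made where the design was genuinely open, and what the synthetic-phantom tests
do and do not demonstrate about real data.

## The pipeline model

A run is the composition *Reader → Sampler → Network → output handler*. The
Reader turns a directory (or CSV manifest) into an ordered subject table and
loads NIfTI volumes into a 5-axis `(x, y, z, time, channel)` container with
the voxel-to-world affine, spacing and orientation codes. During training the
Sampler crops random fixed-shape windows, optionally augmented; the output
handler computes a loss and takes an Adam step. During inference the Sampler
tiles each volume systematically and the Aggregator reassembles per-window
network outputs into a whole-volume result. One coordinate convention is used
throughout: 0-based, half-open `[start, start + shape)`, with spatial axes
ordered `(x, y, z)` exactly as stored in the NIfTI array.

## Window sampling and aggregation

Grid sampling steps each axis by `window − 2·border`, clamping a final start
to `dim − window` when the last regular window does not reach the edge. The
`border` (default 0; 2 voxels in the end-to-end runs) is the margin of every
window discarded at aggregation, the standard defence against convolution
edge effects. Because the *central* regions of edge windows cannot reach the
volume edge, grid sampling first pads the volume by the border on each side
with edge replication; central regions then cover every voxel, which is the
module's load-bearing invariant. Overlapping central regions (from clamping)
are resolved by unweighted averaging for continuous outputs and by argmax of
summed per-class scores for labels, ties toward the lower class index — both
order-invariant rules. The averaging of n identical values reproduces them
only to IEEE rounding (`n·v/n`), so "exact" round-trip checks use a 1e-12
tolerance rather than bit equality.

Uniform sampling is uniform over window *starts*; weighted sampling draws the
window *centre* proportional to a weight map restricted to positions where
the window fits. Undersized volumes are symmetrically edge-padded, never
zero-padded, to avoid out-of-distribution intensities.

## Intensity normalization

Mean/variance normalization standardizes each channel to mean 0, variance 1
(population variance), optionally computing the statistics inside a mask but
transforming all voxels with the same affine map. The default is the whole
volume.

Histogram standardization follows the classic landmark method: probe ranks
{1, 5, 10, …, 90, 95, 99}, cutoffs (1, 99), a standard scale mapping the
probe ranks linearly onto [0, 100]. Training rescales each image's percentile
curve so its endpoints hit the scale ends, clips the landmark values to the
cutoff range, and averages the curves per modality. Transforming a volume
maps its *own* percentile values onto the trained landmark positions by
piecewise-linear interpolation with linear extrapolation beyond the end
landmarks — by construction invariant to affine intensity changes of the
input and nondecreasing. One subtlety: clipping is applied to the landmark
values rather than to the voxel data; the two are equivalent except for
order-statistic interpolation at the cutoff boundary, and the former makes
the single-image self-mapping identity exact.

## Augmentation

A draw is (random per-axis flips) ∘ (independent per-axis rotations, uniform
in a degree range) ∘ (one isotropic scale factor, uniform in a percent
range), composed about the volume centre and applied by pull-back
interpolation — trilinear for images (out-of-field filled with the channel
minimum), nearest-neighbour for labels and weight maps (filled with 0), so
label values are closed under augmentation. The affine metadata is not
updated: augmented windows exist only inside the training loop. At the 16³
window scale used in the tests, the disagreement between linearly blended
image boundaries and nearest-neighbour label boundaries is a one-voxel shell
that is a substantial fraction of a small organ, so the default ranges are
deliberately mild (±10° rotation, 90–110% scale as parameters; the end-to-end
tests train with ±5°, 97–103%). On clinical-resolution data the same shell is
proportionally much smaller and stronger ranges are appropriate.

## Networks, autodiff and losses

No deep-learning framework is used: the package carries a minimal
reverse-mode tape whose nodes hold plain R arrays, with the 3D convolution
forward/backward kernels in C++. Blocks register parameters in a store under
hierarchical scope names (`net/level0/dfs/block1/conv/weight`); invoking a
block again with the same name reuses the same arrays, which is what makes
weight sharing, checkpointing and scope-renamed restores compositional.

`conv_block` is convolution (stride 1, zero padding preserving shape) →
normalization → activation. The normalization is *layer* normalization (per
voxel, across channels) rather than instance normalization: both are
batch-size-independent, but per-window instance statistics erase the absolute
intensity level of a window, and in calibrated images (CT-like phantoms
included) absolute intensity is the dominant class cue — with instance
normalization the reference network measurably fails to recover phantom
organs. A dense feature stack feeds block *i* the concatenation of the stack
input and all previous block outputs, so with `C0` input channels block *i*
sees `C0 + (i−1)·growth` channels and the stack returns `n_blocks·growth`.

The reference segmentation network is V-shaped: per level a dense stack
(2 blocks, growth 8) then 2× average pooling; trilinear 2× upsampling back
up, a 1×1×1 convolutional skip from each level's stack summed in; a 3³ head
block and a 1×1×1 projection to class scores. Depth 2 (two downsamplings)
and growth 8 give roughly 2.5×10⁴ parameters — a desk-scale model trainable
on one CPU in minutes, not a replica of any published architecture. Spatial
dims must be divisible by 2^depth.

Soft Dice uses ε = 10⁻⁵ and averages over all classes including background;
on one-hot inputs it reproduces mean hard Dice to the ε-correction. RMSE is
the plain masked root-mean-square error. Adversarial training alternates a
discriminator step (real-vs-generated cross-entropy on logits) and a
generator step with the non-saturating objective; the update partition is
enforced by scope-filtered optimizers, so each step leaves the other
sub-network bitwise untouched. All fused losses have analytic gradients
verified against central finite differences in the test suite.

## Driver, configuration and reproducibility

Configurations are INI files with strict key checking (a misspelled key is an
error) and every default filled in at resolution; checkpoints embed the full
resolved text, so a checkpoint alone can re-launch inference. One master seed
derives a named RNG stream per component (sampler, augmentation,
initialization, noise) by hashing the stream name, so adding draws in one
component does not shift another's sequence. The training loop draws
`samples_per_volume` windows per iteration and averages their losses — the
mini-batch size, and the main stabilizer of Dice training at small iteration
counts. Checkpoints additionally store RNG stream states and Adam moments,
making a resumed run bitwise identical to an uninterrupted one. Optimizer:
Adam, default learning rate 10⁻³ (the end-to-end runs use 3×10⁻³).

## Evaluation metrics

Surfaces are foreground voxels with a six-connected background neighbour
(the array boundary counts as background); distances are voxel-centre to
voxel-centre, scaled per axis by the spacing, and the two directed
nearest-distance sets are pooled before taking the mean (MAD), maximum
(Hausdorff) and 95th percentile (linear-interpolation convention). Pooling
makes all three symmetric in (segmentation, reference). Ratios that are 0/0
are reported as NaN and kept in the CSV. Region metrics use 26-connected
components with detection defined as any positive overlap by default
(configurable fraction threshold). Compactness is `S^1.5 / V`, a
scale-normalized surface/volume ratio; distances default to voxel units with
millimetres available via the spacing option.

## The phantom generator

Phantoms are `n_organs` non-overlapping ellipsoids (radii 10–25% of the
smallest axis, rejection-sampled centres) on background 0; the label map is
the organ index and the image adds Gaussian noise to per-organ constant
intensities (defaults: 32³ voxels, 3 organs, means 1..3, noise SD 0.1 — i.e.
noise at 10% of the inter-tissue separation). Regression phantoms share the
geometry but map the *organ index* (not the source intensity) through a fixed
affine map `0.5 + 0.75·k` with independent noise, so a regressor must learn a
per-tissue mapping, mimicking cross-modality synthesis. The generator is a
pure function of (spec, n_subjects).

What the phantoms emulate: calibrated absolute intensities (as in CT),
compact organs with known ground truth, multi-subject variation in organ
position and size. What they do not: anatomical shape complexity, intensity
inhomogeneity and bias fields, partial-volume effects, anisotropic voxels,
inter-scanner variation, or class structure where intensity alone is
uninformative. Passing the end-to-end tests therefore demonstrates that the
pipeline is *correctly wired* — losses decrease, windows reassemble, labels
align with images through augmentation — not that the reference network
would segment clinical images.

## Problem sizes in the shipped tests

The end-to-end segmentation check trains on eight 32³ phantoms with 16³
windows, mini-batch 2, 300 iterations, and evaluates on two held-out
phantoms (Dice ≥ 0.90 per organ, repeated over three seeds); the regression
check uses the same geometry with the RMSE loss (held-out MAE ≤ 2× the noise
SD). These sizes were chosen as the smallest at which the recovery behaviour
is stable across seeds; unit and property tests run on volumes of a few
thousand voxels with brute-force oracles.

## Known limitations

Single-process, single-device execution; no data-queue threading. Batch
normalization is deliberately absent (batch size is 1–4 windows). The
reference network is intentionally small; plugging in external architectures
is supported through network factories named in the configuration. DICOM is
out of scope (NIfTI-1 only), as are deformable augmentation, resampling to
isotropic grids, and hyper-parameter search.
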