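# voxpipe

Patch-based deep learning pipelines for volumetric medical images, in R.

Training a convolutional network on 3D medical images takes much more than a
network: corresponding image/label files must be discovered and loaded with
their spatial metadata, intensities normalized, training windows sampled and
augmented, per-window network outputs reassembled into whole volumes, and the
resulting segmentations evaluated with the field's standard metrics. voxpipe
implements that whole pipeline as composable pieces behind a single
configuration-driven driver, together with a small reverse-mode automatic
differentiation engine (with C++ 3D convolution kernels) so the networks train
on a plain CPU with no external deep-learning framework. Synthetic multi-organ
phantom generators make every stage runnable and testable without clinical
data.

It is aimed at method developers who want a transparent, fully inspectable
reference implementation of the patch pipeline itself — samplers, aggregators,
losses, metrics — rather than a production training system.

## The pipeline

* **Volume I/O** — NIfTI-1 reading/writing via RNifti with a 5-axis
  `(x, y, z, time, channel)` container carrying the 4×4 voxel-to-world affine,
  spacing and orientation codes; dataset assembly by filename-pattern
  discovery or CSV manifest; lossless reorientation by axis permutation/flip.
* **Normalization & augmentation** — per-channel mean/variance
  standardization; trained histogram-landmark standardization (percentile
  landmarks averaged over the training set, piecewise-linear remapping,
  invariant to affine intensity changes); random affine augmentation
  (flips ∘ per-axis rotations ∘ isotropic scaling about the volume centre),
  applied identically to all sections with linear (image) or
  nearest-neighbour (label) resampling.
* **Sampling & aggregation** — uniform, weighted, grid and resize samplers
  emitting windows of corresponding per-section arrays; a grid aggregator
  that keeps each window's central region (window − 2·border), averages
  overlaps, and inverts the sampling exactly; noise sampling for generative
  models.
* **Networks & losses** — named-scope blocks with shared parameters:
  `conv_block` (convolution → layer norm → activation), `dense_feature_stack`
  (block *i* consumes the concatenation of the input and all previous block
  outputs), and a small V-shaped reference segmentation network
  (dense stacks per level, 2× average-pool downsampling, trilinear
  upsampling, convolutional skip connections). Losses: soft multi-class Dice
  `1 − mean_c (2Σp_c g_c + ε)/(Σp_c + Σg_c + ε)`, RMSE, and alternating
  adversarial optimization with the update partition enforced by
  scope-filtered Adam optimizers. Checkpoints store the scope → tensor map
  plus the fully resolved configuration, and support scope-renamed restores.
* **Evaluation** — per-subject, per-label tidy reports: Dice, Jaccard,
  sensitivity/specificity/accuracy, volumes and relative volume difference,
  symmetric surface distances (mean absolute, Hausdorff, 95th-percentile
  Hausdorff on the pooled bidirectional distances), region-wise detection
  metrics (26-connected components), and descriptive region statistics.
* **Driver** — INI configuration (strict keys, all defaults resolved
  explicitly) and actions `train`, `inference`, `evaluation`,
  `linear_interpolation`; one master seed feeding named RNG streams per
  component, giving bitwise-reproducible and exactly resumable runs.

## Worked example

Train the reference network on four synthetic single-organ phantoms, then run
sliding-window inference and evaluation on a held-out phantom:

```r
library(voxpipe)

train_dir <- file.path(tempdir(), "train"); test_dir <- file.path(tempdir(), "test")
write_phantom_dataset(phantom_spec(seed = 1, shape = c(16, 16, 16), n_organs = 1),
                      4, train_dir)
write_phantom_dataset(phantom_spec(seed = 99, shape = c(16, 16, 16), n_organs = 1),
                      1, test_dir)

cfg_file <- file.path(tempdir(), "demo.ini")
writeLines(c("[system]",  "action = train",
             paste0("model_dir = ", file.path(tempdir(), "model")), "seed = 7",
             "[network]",  "name = reference_segnet", "n_classes = 2", "growth = 4",
             "[training]", "lr = 0.01", "iterations = 80",
             "spatial_window_size = 8 8 8", "normalisation = none",
             "[inference]","spatial_window_size = 8 8 8", "border = 1 1 1",
             "[image]",    paste0("path = ", train_dir), "pattern = _img",
             "[label]",    paste0("path = ", train_dir), "pattern = _seg"), cfg_file)

fit <- run_training(cfg_file)
cat(sprintf("Dice loss: %.3f (step 1) -> %.3f (step 80)\n",
            fit$log$loss[1], fit$log$loss[80]))

inf <- parse_config(cfg_file, c("system.action" = "inference",
                                "image.path" = test_dir, "label.path" = test_dir))
run_inference(inf)
report <- run_evaluation(parse_config(inf, c("system.action" = "evaluation")))
report[report$metric %in% c("dice", "hausdorff95") & report$subject_id != "median", ]
```

Output (seconds on one CPU):

```
Dice loss: 0.852 (step 1) -> 0.142 (step 80)
# A tibble: 2 x 4
  subject_id label metric      value
  <chr>      <dbl> <chr>       <dbl>
1 sub001         1 dice        0.935
2 sub001         1 hausdorff95 1
```

The training loss is the soft Dice loss of sampled 8³ windows (falling from
0.85 towards 0 as the organ is learned); the report rows say the held-out
organ is recovered with Dice 0.94 and a 95th-percentile surface error of one
voxel. Larger runs (32³ phantoms, 3 organs, 300 iterations) reach per-organ
Dice ≥ 0.94; see the test suite.

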