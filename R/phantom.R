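# Synthetic multi-organ phantoms: paired image/label/regression-target
# volumes with known ground truth, so every pipeline stage runs without
# external data.

#' Phantom specification
#'
#' Describes a synthetic multi-organ volume: `n_organs` non-overlapping
#' random ellipsoids (radii 10-25% of the smallest axis, rejection-sampled
#' centres) on a zero background; the label map holds the organ index and
#' the image a per-organ constant intensity plus Gaussian noise.  The
#' defaults — 32^3 voxels, 3 organs, unit intensity separation with noise
#' standard deviation 0.1 of that separation — are the conditions the
#' package's end-to-end tests train and evaluate under.
#'
#' @param shape 3 ints (>= 16 per axis for multi-organ phantoms).
#' @param n_organs number of organs (<= 20).
#' @param intensity_means per-organ mean intensities (background is 0);
#'   default `1:n_organs`.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param spacing voxel spacing (mm).
#' @param seed integer seed making the phantom deterministic.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32, 32), n_organs = 3,
                         intensity_means = NULL, noise_sd = 0.1,
                         spacing = c(1, 1, 1), seed = 1) {
  shape <- as_int3(shape, "shape")
  vp_assert(n_organs >= 1 && n_organs <= 20, "n_organs must be in 1..20")
  vp_assert(n_organs == 1 || all(shape >= 16),
            "multi-organ phantoms need shape >= 16 per axis")
  vp_assert(noise_sd >= 0, "noise_sd must be >= 0")
  intensity_means <- intensity_means %||% seq_len(n_organs)
  vp_assert(length(intensity_means) == n_organs,
            "need one intensity mean per organ")
  structure(list(shape = shape, n_organs = as.integer(n_organs),
                 intensity_means = intensity_means, noise_sd = noise_sd,
                 spacing = spacing, seed = as.integer(seed)),
            class = "phantom_spec")
}

# rejection-sample non-overlapping ellipsoids; returns the label array
sample_organ_labels <- function(spec, rng) {
  shape <- spec$shape
  rmin <- 0.10 * min(shape); rmax <- 0.25 * min(shape)
  g <- coord_grid(shape)
  lab <- integer(prod(shape))
  placed <- 0L
  tries <- 0L
  while (placed < spec$n_organs) {
    tries <- tries + 1L
    if (tries > 1000L) {
      vp_stop("could not place %d non-overlapping organs in shape %s; use a larger shape",
              spec$n_organs, paste(shape, collapse = "x"))
    }
    par <- with_rng(rng, list(
      radii = runif(3, rmin, rmax),
      centre = runif(3, rmax, shape - 1 - rmax)))
    inside <- colSums((t(g) - par$centre)^2 / par$radii^2) <= 1
    if (any(lab[inside] != 0L)) next
    placed <- placed + 1L
    lab[inside] <- placed
  }
  array(lab, dim = shape)
}

phantom_affine <- function(spec) {
  a <- diag(4)
  a[1:3, 1:3] <- diag(spec$spacing)
  a
}

#' Generate a phantom image/label pair
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` and `label` [image_volume()]s; organ `k` voxels
#'   have image intensity `intensity_means[k] + N(0, noise_sd)`, background
#'   has mean 0.
#' @export
generate_phantom <- function(spec) {
  vp_assert(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  rng <- rng_stream(spec$seed)
  lab <- sample_organ_labels(spec, rng)
  means <- c(0, spec$intensity_means)[lab + 1L]
  img <- means
  if (spec$noise_sd > 0) {
    img <- img + with_rng(rng, rnorm(length(lab), 0, spec$noise_sd))
  }
  aff <- phantom_affine(spec)
  list(image = image_volume(array(img, dim = spec$shape), aff, "image"),
       label = image_volume(array(as.double(lab), dim = spec$shape), aff, "label"))
}

# per-organ target intensities: a fixed affine map of the organ index
# (NOT of the source intensity), so a regressor must use spatial context
regression_target_map <- function(n_organs) 0.5 + 0.75 * (0:n_organs)

#' Generate a phantom regression pair
#'
#' Source and target share the same organ geometry; the target intensity of
#' organ `k` is the fixed affine map `0.5 + 0.75 * k` of the organ index
#' (background uses `k = 0`), with noise independent of the source's.  This
#' emulates cross-modality synthesis (e.g. MR to pseudo-CT): the intensity
#' mapping is per tissue, not a pointwise function of the source image.
#'
#' @param spec a [phantom_spec()].
#' @return list with `source`, `target` and `label` [image_volume()]s.
#' @export
generate_regression_pair <- function(spec) {
  vp_assert(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  rng <- rng_stream(spec$seed)
  lab <- sample_organ_labels(spec, rng)
  src_means <- c(0, spec$intensity_means)[lab + 1L]
  tgt_means <- regression_target_map(spec$n_organs)[lab + 1L]
  src <- src_means; tgt <- tgt_means
  if (spec$noise_sd > 0) {
    src <- src + with_rng(rng, rnorm(length(lab), 0, spec$noise_sd))
    tgt <- tgt + with_rng(rng, rnorm(length(lab), 0, spec$noise_sd))
  }
  aff <- phantom_affine(spec)
  list(source = image_volume(array(src, dim = spec$shape), aff, "image"),
       target = image_volume(array(tgt, dim = spec$shape), aff, "image"),
       label = image_volume(array(as.double(lab), dim = spec$shape), aff, "label"))
}

#' Normalized coordinate conditioning map
#'
#' A 3-channel volume in which channel k holds the voxel coordinate along
#' axis k normalized to `[0, 1]` — the conditioning input of the spatially
#' conditioned generative application.
#'
#' @param shape 3 positive ints.
#' @return a 3-channel `image_volume`.
#' @export
generate_conditioning_map <- function(shape) {
  shape <- as_int3(shape, "shape")
  vp_assert(all(shape >= 1), "shape must be positive")
  g <- coord_grid(shape)
  den <- pmax(shape - 1, 1)
  arr <- array(0, dim = c(shape, 3))
  for (k in 1:3) arr[, , , k] <- array(g[, k] / den[k], dim = shape)
  image_volume(array(arr, dim = c(shape, 1, 3)), section = "image",
               modality_names = c("coord_x", "coord_y", "coord_z"))
}

#' Write a phantom dataset to disk
#'
#' Writes `n_subjects` phantom pairs as `<subject>_img.nii.gz` /
#' `<subject>_seg.nii.gz` plus a `manifest.csv`, exercising both dataset
#' discovery paths ([discover_dataset()] with patterns `_img` / `_seg`, and
#' [load_manifest()]).  Per-subject seeds derive from `spec$seed`, so the
#' dataset is a pure function of `(spec, n_subjects)`.
#'
#' @param spec a [phantom_spec()]; its `seed` is the master seed.
#' @param n_subjects number of subjects.
#' @param out_dir output directory (created).
#' @param kind `"segmentation"` (image + label) or `"regression"`
#'   (source image + target + label; target saved as
#'   `<subject>_tgt.nii.gz` and listed in the manifest).
#' @return the manifest path, invisibly.
#' @export
write_phantom_dataset <- function(spec, n_subjects, out_dir,
                                  kind = c("segmentation", "regression")) {
  kind <- match.arg(kind)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("sub%03d", seq_len(n_subjects))
  rows <- list()
  for (i in seq_len(n_subjects)) {
    sub_spec <- spec
    sub_spec$seed <- (spec$seed + 7919L * i) %% (2^31 - 1)
    img_path <- file.path(out_dir, paste0(ids[i], "_img.nii.gz"))
    seg_path <- file.path(out_dir, paste0(ids[i], "_seg.nii.gz"))
    if (kind == "segmentation") {
      ph <- generate_phantom(sub_spec)
      write_volume(ph$image, img_path)
      write_volume(ph$label, seg_path)
      rows[[i]] <- data.frame(subject_id = ids[i],
                              image = basename(img_path),
                              label = basename(seg_path))
    } else {
      ph <- generate_regression_pair(sub_spec)
      tgt_path <- file.path(out_dir, paste0(ids[i], "_tgt.nii.gz"))
      write_volume(ph$source, img_path)
      write_volume(ph$target, tgt_path)
      write_volume(ph$label, seg_path)
      rows[[i]] <- data.frame(subject_id = ids[i],
                              image = basename(img_path),
                              target = basename(tgt_path),
                              label = basename(seg_path))
    }
  }
  manifest <- file.path(out_dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE,
                   quote = FALSE)
  invisible(manifest)
}
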