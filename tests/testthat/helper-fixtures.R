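# Shared fixtures and independent oracles, all built in code at test time.

vx <- asNamespace("voxpipe")

# a small random image volume
rand_volume <- function(shape = c(6, 5, 4), channels = 1, seed = 1,
                        section = "image", affine = diag(4)) {
  set.seed(seed)
  image_volume(array(rnorm(prod(shape) * channels), dim = c(shape, channels)),
               affine = affine, section = section)
}

# write a NIfTI with a given affine, return the path
write_tmp_nifti <- function(arr, affine = diag(4), dir = NULL,
                            name = "vol.nii.gz", section = "image") {
  if (is.null(dir)) {
    dir <- tempfile("nii")
    dir.create(dir)
  }
  path <- file.path(dir, name)
  write_volume(image_volume(arr, affine = affine, section = section), path)
  path
}

# random binary mask with at least one foreground voxel
rand_mask <- function(shape, p = 0.2, seed = 1) {
  set.seed(seed)
  m <- array(runif(prod(shape)) < p, dim = shape)
  if (!any(m)) m[1] <- TRUE
  m
}

# ---- independent oracles -----------------------------------------------------

# brute-force surface extraction: explicit 6-neighbour loop
bf_surface_coords <- function(mask) {
  d <- dim(mask)
  out <- NULL
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    nb <- c(
      if (x > 1) mask[x - 1, y, z] else FALSE,
      if (x < d[1]) mask[x + 1, y, z] else FALSE,
      if (y > 1) mask[x, y - 1, z] else FALSE,
      if (y < d[2]) mask[x, y + 1, z] else FALSE,
      if (z > 1) mask[x, y, z - 1] else FALSE,
      if (z < d[3]) mask[x, y, z + 1] else FALSE)
    if (!all(nb)) out <- rbind(out, c(x, y, z) - 1)
  }
  out
}

# brute-force all-pairs symmetric surface distances
bf_surface_distances <- function(seg, ref, spacing = c(1, 1, 1)) {
  a <- bf_surface_coords(seg)
  b <- bf_surface_coords(ref)
  scale_rows <- function(m) sweep(m, 2, spacing, `*`)
  a <- scale_rows(a); b <- scale_rows(b)
  dmat <- sqrt(outer(a[, 1], b[, 1], `-`)^2 +
               outer(a[, 2], b[, 2], `-`)^2 +
               outer(a[, 3], b[, 3], `-`)^2)
  pooled <- c(apply(dmat, 1, min), apply(dmat, 2, min))
  list(mean_absolute_distance = mean(pooled),
       hausdorff = max(pooled),
       hausdorff95 = unname(quantile(pooled, 0.95, type = 7)))
}

# brute-force overlap metrics from explicit voxel loops
bf_overlap <- function(seg, ref, label_value) {
  s <- as.vector(seg) == label_value
  r <- as.vector(ref) == label_value
  tp <- sum(s & r); fp <- sum(s & !r); fn <- sum(!s & r); tn <- sum(!s & !r)
  list(dice = if (2 * tp + fp + fn == 0) NaN else 2 * tp / (2 * tp + fp + fn),
       jaccard = if (tp + fp + fn == 0) NaN else tp / (tp + fp + fn),
       sensitivity = if (tp + fn == 0) NaN else tp / (tp + fn),
       specificity = if (tn + fp == 0) NaN else tn / (tn + fp),
       accuracy = (tp + tn) / (tp + fp + fn + tn))
}

# piecewise-linear landmark mapping oracle via stats::approx on tiny arrays
bf_percentile_map <- function(x, percentiles, std_scale) {
  knots <- quantile(x, percentiles / 100, names = FALSE)
  approx(knots, std_scale, xout = x, rule = 2)$y
}
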