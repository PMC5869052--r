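# Samplers: convert a subject's corresponding volumes into a stream of
# sample windows (random during training, systematic during inference).

# normalize sampler input: named list of image_volume or (x,y,z,C) arrays
# -> list(arrays = named list of 4D arrays, sections = named character)
as_section_arrays <- function(vols) {
  vp_assert(length(vols) >= 1 && !is.null(names(vols)),
            "samplers need a named list of volumes")
  arrays <- lapply(vols, function(v)
    if (inherits(v, "image_volume")) vol_array4(v) else v)
  sections <- vapply(names(vols), function(nm) {
    v <- vols[[nm]]
    if (inherits(v, "image_volume")) v$section
    else if (nm %in% c("label", "weight")) nm else "image"
  }, character(1))
  shapes <- vapply(arrays, function(a) dim(a)[1:3], integer(3))
  vp_assert(all(shapes == shapes[, 1]), "sections must share spatial shape")
  list(arrays = arrays, sections = sections, shape = shapes[, 1])
}

new_sample_window <- function(subject_id, start, shape, arrays, placement_valid,
                              pad_before = c(0L, 0L, 0L),
                              original_shape = NULL, sections = NULL) {
  structure(list(subject_id = subject_id, start = as.integer(start),
                 shape = as.integer(shape), arrays = arrays,
                 placement_valid = placement_valid,
                 pad_before = as.integer(pad_before),
                 original_shape = original_shape, sections = sections),
            class = "sample_window")
}

#' @export
print.sample_window <- function(x, ...) {
  cat(sprintf("<sample_window> subject %s start (%s) shape (%s) sections: %s\n",
              x$subject_id %||% "?", paste(x$start, collapse = ","),
              paste(x$shape, collapse = ","),
              paste(names(x$arrays), collapse = ", ")))
  invisible(x)
}

# edge-replication padding: `border` voxels on both sides, then symmetric
# extra padding up to a minimum spatial shape
pad_arrays <- function(arrays, shape, min_shape, border = c(0L, 0L, 0L)) {
  need <- pmax(min_shape - (shape + 2L * border), 0L)
  pad_before <- border + need %/% 2L
  pad_after <- border + need - need %/% 2L
  if (all(pad_before == 0L) && all(pad_after == 0L)) {
    return(list(arrays = arrays, pad_before = c(0L, 0L, 0L)))
  }
  idx <- lapply(1:3, function(k)
    c(rep(1L, pad_before[k]), seq_len(shape[k]), rep(shape[k], pad_after[k])))
  arrays <- lapply(arrays, function(a) a[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE])
  list(arrays = arrays, pad_before = pad_before)
}

crop_window <- function(arrays, start, wshape) {
  lapply(arrays, function(a)
    a[start[1] + seq_len(wshape[1]), start[2] + seq_len(wshape[2]),
      start[3] + seq_len(wshape[3]), , drop = FALSE])
}

#' Uniform random window sampler
#'
#' Draws `n` windows whose starts are uniform over all valid positions
#' (every section cropped with the same start/shape).  Volumes smaller than
#' the window are symmetrically edge-padded when `pad = TRUE`, otherwise an
#' error is raised.
#'
#' @param vols named list of [image_volume()]s or `(x,y,z,C)` arrays sharing
#'   spatial shape.
#' @param window_shape 3 ints (or 1 recycled).
#' @param n number of windows.
#' @param rng an [rng_stream()].
#' @param pad allow padding of undersized volumes.
#' @param subject_id carried into the windows.
#' @return list of `sample_window`.
#' @export
uniform_sample <- function(vols, window_shape, n, rng, pad = TRUE,
                           subject_id = NULL) {
  sa <- as_section_arrays(vols)
  w <- as_int3(window_shape, "window shape")
  vp_assert(all(w >= 1), "window shape must be positive")
  if (any(w > sa$shape) && !pad) {
    vp_stop("window (%s) larger than volume (%s) and padding disabled",
            paste(w, collapse = "x"), paste(sa$shape, collapse = "x"))
  }
  padded <- pad_arrays(sa$arrays, sa$shape, w)
  pshape <- pmax(sa$shape, w)
  maxs <- pshape - w
  starts <- with_rng(rng, {
    m <- matrix(0L, n, 3)
    for (k in 1:3) m[, k] <- sample.int(maxs[k] + 1L, n, replace = TRUE) - 1L
    m
  })
  lapply(seq_len(n), function(i) {
    st <- starts[i, ]
    new_sample_window(subject_id, st, w,
                      crop_window(padded$arrays, st, w),
                      placement_valid = all(padded$pad_before == 0L),
                      pad_before = padded$pad_before,
                      original_shape = sa$shape, sections = sa$sections)
  })
}

#' Weighted random window sampler
#'
#' Window centres are drawn with probability proportional to the weight map
#' at the centre voxel, restricted to positions where the window fits.
#'
#' @inheritParams uniform_sample
#' @param weight_section name of the section holding the (nonnegative,
#'   not-all-zero) weight map.
#' @return list of `sample_window`.
#' @export
weighted_sample <- function(vols, window_shape, weight_section = "weight",
                            n = 1L, rng = rng_stream(1), subject_id = NULL) {
  sa <- as_section_arrays(vols)
  w <- as_int3(window_shape, "window shape")
  vp_assert(weight_section %in% names(sa$arrays),
            "weight section '%s' not present", weight_section)
  vp_assert(all(w <= sa$shape), "window larger than volume")
  wmap <- sa$arrays[[weight_section]][, , , 1]
  dim(wmap) <- sa$shape
  vp_assert(all(wmap >= 0), "weight map must be nonnegative")
  off <- w %/% 2L                     # centre = start + off
  nvalid <- sa$shape - w + 1L
  sub <- wmap[off[1] + seq_len(nvalid[1]), off[2] + seq_len(nvalid[2]),
              off[3] + seq_len(nvalid[3]), drop = FALSE]
  pw <- as.vector(sub)
  vp_assert(sum(pw) > 0, "all-zero weights over valid window centres")
  picks <- with_rng(rng, sample.int(length(pw), n, replace = TRUE, prob = pw))
  lapply(picks, function(p) {
    p0 <- p - 1L
    st <- c(p0 %% nvalid[1],
            (p0 %/% nvalid[1]) %% nvalid[2],
            p0 %/% (nvalid[1] * nvalid[2]))
    new_sample_window(subject_id, st, w, crop_window(sa$arrays, st, w),
                      placement_valid = TRUE, original_shape = sa$shape,
                      sections = sa$sections)
  })
}

grid_axis_starts <- function(dim, window, border) {
  stride <- window - 2L * border
  starts <- seq.int(0L, max(dim - window, 0L), by = max(stride, 1L))
  if (starts[length(starts)] + window < dim) starts <- c(starts, dim - window)
  unique(as.integer(starts))
}

#' Systematic grid window sampler
#'
#' Tiles the volume with windows whose central regions (the window shrunk by
#' `border` on every side) cover every voxel.  Per axis the starts step by
#' `window - 2 * border`, with a final start clamped to `dim - window` when
#' the last regular window does not reach the edge (edge windows may then
#' overlap; the aggregator averages).  Windows are emitted in lexicographic
#' `(x, y, z)` order.  Volumes smaller than the window are symmetrically
#' edge-padded and flagged `placement_valid = FALSE`.
#'
#' @inheritParams uniform_sample
#' @param border 3 ints, margin discarded at aggregation.
#' @return ordered list of `sample_window`.
#' @export
grid_sample <- function(vols, window_shape, border = 0L, subject_id = NULL) {
  sa <- as_section_arrays(vols)
  w <- as_int3(window_shape, "window shape")
  b <- as_int3(border, "border")
  vp_assert(all(b >= 0), "border must be nonnegative")
  vp_assert(all(w >= 2L * b + 1L), "window must be at least 2*border + 1 per axis")
  # pad by the border on both sides (so central regions cover the volume
  # edges), and further if the volume is smaller than the window
  padded <- pad_arrays(sa$arrays, sa$shape, w, border = b)
  pshape <- pmax(sa$shape + 2L * b, w)
  ax <- lapply(1:3, function(k) grid_axis_starts(pshape[k], w[k], b[k]))
  out <- list()
  for (sx in ax[[1]]) for (sy in ax[[2]]) for (sz in ax[[3]]) {
    st <- c(sx, sy, sz)
    st_orig <- st - padded$pad_before
    out[[length(out) + 1L]] <- new_sample_window(
      subject_id, st, w, crop_window(padded$arrays, st, w),
      placement_valid = all(st_orig >= 0L & st_orig + w <= sa$shape),
      pad_before = padded$pad_before,
      original_shape = sa$shape, sections = sa$sections)
  }
  out
}

#' Whole-volume resize sampler
#'
#' Rescales every section of the full volume to a fixed window shape (linear
#' for images, nearest-neighbour for labels/weights), recording the original
#' shape so [resize_aggregate()] can invert the operation.
#'
#' @inheritParams uniform_sample
#' @param target_shape 3 ints.
#' @return a single `sample_window` with start `(0,0,0)`.
#' @export
resize_sample <- function(vols, target_shape, subject_id = NULL) {
  sa <- as_section_arrays(vols)
  t <- as_int3(target_shape, "target shape")
  vp_assert(all(t >= 1), "target shape must be positive")
  arrays <- lapply(names(sa$arrays), function(nm) {
    interp <- if (sa$sections[[nm]] %in% c("label", "weight")) "nearest" else "linear"
    resize_array(sa$arrays[[nm]], t, interp)
  })
  names(arrays) <- names(sa$arrays)
  new_sample_window(subject_id, c(0L, 0L, 0L), t, arrays,
                    placement_valid = all(t == sa$shape),
                    original_shape = sa$shape, sections = sa$sections)
}

#' Gaussian noise sampler
#'
#' Draws `n` i.i.d. standard-normal latent vectors of dimension `dim`
#' (the model-parameter input of the conditional generative application).
#'
#' @param dim latent dimension (>= 1).
#' @param n number of samples.
#' @param rng an [rng_stream()].
#' @return an `n x dim` matrix; rows are samples.
#' @export
sample_noise <- function(dim, n, rng) {
  vp_assert(dim >= 1, "dim must be >= 1")
  with_rng(rng, matrix(rnorm(n * dim), nrow = n, ncol = dim))
}
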