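#' Random affine augmentation parameters
#'
#' Container for the spatial augmentation ranges: random flips on a subset of
#' axes, independent per-axis rotations drawn uniformly from
#' `rotation_range_deg`, and one isotropic scale factor drawn uniformly from
#' `scaling_range_pct` (percent, 100 = unit scale).
#'
#' @param flip_axes subset of `c(1, 2, 3)` (1-based spatial axes), possibly
#'   empty.
#' @param rotation_range_deg length-2 interval within `[-180, 180]` degrees.
#' @param scaling_range_pct positive length-2 interval in percent.
#' @return an `augmentation_params` object.
#' @export
augmentation_params <- function(flip_axes = integer(0),
                                rotation_range_deg = c(-10, 10),
                                scaling_range_pct = c(90, 110)) {
  if (length(rotation_range_deg) == 1) rotation_range_deg <- rep(rotation_range_deg, 2)
  if (length(scaling_range_pct) == 1) scaling_range_pct <- rep(scaling_range_pct, 2)
  vp_assert(all(rotation_range_deg >= -180 & rotation_range_deg <= 180) &&
            diff(rotation_range_deg) >= 0, "rotation range must lie within [-180, 180]")
  vp_assert(all(scaling_range_pct > 0) && diff(scaling_range_pct) >= 0,
            "scaling range must be positive")
  vp_assert(all(flip_axes %in% 1:3), "flip axes must be within 1..3")
  structure(list(flip_axes = as.integer(flip_axes),
                 rotation_range_deg = rotation_range_deg,
                 scaling_range_pct = scaling_range_pct),
            class = "augmentation_params")
}

rot3 <- function(axis, theta) {
  c <- cos(theta); s <- sin(theta)
  R <- diag(3)
  ij <- setdiff(1:3, axis)
  R[ij[1], ij[1]] <- c; R[ij[2], ij[2]] <- c
  R[ij[1], ij[2]] <- -s; R[ij[2], ij[1]] <- s
  R
}

#' Draw one random affine spatial transform
#'
#' Composes (random per-axis flips) x (rotations about each spatial axis with
#' angles drawn uniformly from the rotation range) x (one isotropic scale
#' drawn uniformly from the scaling range).  The returned 4x4 matrix has zero
#' translation; [apply_transform()] applies it about the volume centre.
#' Deterministic given the stream state of `rng`.
#'
#' @param params an [augmentation_params()].
#' @param rng an [rng_stream()].
#' @return a 4x4 transform matrix.
#' @export
sample_affine <- function(params, rng) {
  vp_assert(inherits(params, "augmentation_params"), "params must be augmentation_params")
  draws <- with_rng(rng, {
    list(flips = runif(length(params$flip_axes)) < 0.5,
         angles = runif(3, params$rotation_range_deg[1], params$rotation_range_deg[2]),
         scale = runif(1, params$scaling_range_pct[1], params$scaling_range_pct[2]) / 100)
  })
  Fm <- diag(3)
  for (k in seq_along(params$flip_axes)) {
    if (draws$flips[k]) Fm[params$flip_axes[k], params$flip_axes[k]] <- -1
  }
  R <- rot3(1, draws$angles[1] * pi / 180) %*%
       rot3(2, draws$angles[2] * pi / 180) %*%
       rot3(3, draws$angles[3] * pi / 180)
  A <- diag(4)
  A[1:3, 1:3] <- Fm %*% R %*% (draws$scale * diag(3))
  A
}

#' Apply one spatial transform to corresponding volumes
#'
#' Resamples every section with the same transform (pull-back interpolation
#' about the volume centre): image sections by trilinear interpolation,
#' label/weight sections by nearest-neighbour so the output label set stays a
#' subset of the input label set.  Out-of-field voxels are filled with the
#' section's per-channel minimum (image) or 0 (label/weight).  Augmented samples are
#' training-only, so the affine metadata is left untouched.
#'
#' @param vols a named list of [image_volume()]s (or plain `(x,y,z,C)` arrays
#'   when `sections` is given) sharing spatial shape.
#' @param transform 4x4 matrix, e.g. from [sample_affine()].
#' @param sections per-element section names when `vols` are plain arrays.
#' @return list of transformed volumes/arrays in input order.
#' @export
apply_transform <- function(vols, transform, sections = NULL) {
  vp_assert(abs(det(transform)) > 1e-12, "transform is not invertible")
  one <- function(v, sec) {
    if (inherits(v, "image_volume")) {
      arr <- vol_array4(v)
      sec <- v$section
    } else arr <- v
    if (is.null(sec)) sec <- "image"
    interp <- if (sec %in% c("label", "weight")) "nearest" else "linear"
    fill <- if (sec %in% c("label", "weight")) 0 else apply(arr, 4, min)
    res <- resample_pullback(arr, transform, interp, fill)
    if (inherits(v, "image_volume")) {
      d5 <- dim(v$data)
      dim(res) <- d5
      v$data <- res
      v
    } else res
  }
  shapes <- vapply(vols, function(v)
    if (inherits(v, "image_volume")) vol_shape(v) else dim(v)[1:3], integer(3))
  vp_assert(all(shapes == shapes[, 1]), "all volumes must share spatial shape")
  if (is.null(sections)) sections <- rep(list(NULL), length(vols))
  out <- mapply(one, vols, sections, SIMPLIFY = FALSE)
  names(out) <- names(vols)
  out
}
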