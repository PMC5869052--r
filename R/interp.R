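# Resampling primitives shared by augmentation, resize sampling and the
# bilinear upsampling layer.  Arrays are (x, y, z, channel); coordinates are
# 0-based voxel indices.

# Sample an (x,y,z,C) array at an N x 3 matrix of continuous voxel
# coordinates.  Points outside [0, n-1] on any axis get `fill` (a scalar or
# one value per channel).
interp_at <- function(arr, coords, interpolation = "linear", fill = 0) {
  d <- dim(arr)
  nc <- d[4]
  n <- nrow(coords)
  arrm <- matrix(arr, ncol = nc)
  inside <- coords[, 1] >= 0 & coords[, 1] <= d[1] - 1 &
            coords[, 2] >= 0 & coords[, 2] <= d[2] - 1 &
            coords[, 3] >= 0 & coords[, 3] <= d[3] - 1
  out <- matrix(fill, n, nc, byrow = length(fill) > 1)
  if (!any(inside)) return(out)
  p <- coords[inside, , drop = FALSE]
  if (interpolation == "nearest") {
    i <- round(p)
    lin <- 1 + i[, 1] + d[1] * (i[, 2] + d[2] * i[, 3])
    out[inside, ] <- arrm[lin, , drop = FALSE]
  } else {
    i0 <- floor(p)
    f <- p - i0
    acc <- matrix(0, nrow(p), nc)
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      ix <- pmin(i0[, 1] + cx, d[1] - 1)
      iy <- pmin(i0[, 2] + cy, d[2] - 1)
      iz <- pmin(i0[, 3] + cz, d[3] - 1)
      w <- (if (cx == 1) f[, 1] else 1 - f[, 1]) *
           (if (cy == 1) f[, 2] else 1 - f[, 2]) *
           (if (cz == 1) f[, 3] else 1 - f[, 3])
      keep <- w > 0
      if (!any(keep)) next
      lin <- 1 + ix[keep] + d[1] * (iy[keep] + d[2] * iz[keep])
      acc[keep, ] <- acc[keep, ] + w[keep] * arrm[lin, , drop = FALSE]
    }
    out[inside, ] <- acc
  }
  out
}

# full 0-based coordinate grid for a spatial shape, as an N x 3 matrix in
# column-major (x fastest) order, matching array vectorization
coord_grid <- function(shape) {
  g <- expand.grid(x = seq_len(shape[1]) - 1,
                   y = seq_len(shape[2]) - 1,
                   z = seq_len(shape[3]) - 1)
  as.matrix(g)
}

# Pull-back resampling of an (x,y,z,C) array under a forward spatial map
# given by 4x4 `transform`, composed about the volume centre.
resample_pullback <- function(arr, transform, interpolation = "linear", fill = 0) {
  d <- dim(arr)
  centre <- (d[1:3] - 1) / 2
  inv <- solve(transform)
  out_coords <- coord_grid(d[1:3])
  rel <- sweep(out_coords, 2, centre)
  src <- cbind(rel, 1) %*% t(inv[1:3, ])
  src <- sweep(src, 2, centre, `+`)
  vals <- interp_at(arr, src, interpolation, fill)
  array(vals, dim = d)
}

# Rescale an (x,y,z,C) array to a new spatial shape (half-pixel-centre
# convention, so constants are preserved and shape-identity is exact).
resize_array <- function(arr, target_shape, interpolation = "linear") {
  d <- dim(arr)
  target_shape <- as_int3(target_shape, "target shape")
  vp_assert(all(target_shape >= 1), "target shape must be positive")
  if (all(target_shape == d[1:3])) return(arr)
  scale <- d[1:3] / target_shape
  g <- coord_grid(target_shape)
  src <- sweep(sweep(g, 2, 0.5, `+`), 2, scale, `*`) - 0.5
  vals <- interp_at(arr, src, interpolation, fill = 0)
  # clamp half-pixel edge coordinates back into the field of view
  outside <- src[, 1] < 0 | src[, 1] > d[1] - 1 |
             src[, 2] < 0 | src[, 2] > d[2] - 1 |
             src[, 3] < 0 | src[, 3] > d[3] - 1
  if (any(outside)) {
    clamped <- src
    for (k in 1:3) clamped[, k] <- pmin(pmax(clamped[, k], 0), d[k] - 1)
    vals[outside, ] <- interp_at(arr, clamped[outside, , drop = FALSE],
                                 interpolation, fill = 0)
  }
  array(vals, dim = c(target_shape, d[4]))
}

# Dense interpolation matrix for factor-2 trilinear upsampling along one axis
# (half-pixel-centre convention); used with its transpose as the backward pass.
upsample2_matrix <- function(n) {
  m <- 2L * n
  U <- matrix(0, m, n)
  for (o in seq_len(m) - 1) {
    p <- (o + 0.5) / 2 - 0.5
    i0 <- floor(p)
    f <- p - i0
    i0c <- min(max(i0, 0), n - 1)
    i1c <- min(max(i0 + 1, 0), n - 1)
    U[o + 1, i0c + 1] <- U[o + 1, i0c + 1] + (1 - f)
    U[o + 1, i1c + 1] <- U[o + 1, i1c + 1] + f
  }
  U
}

# apply a matrix M (m x n) along spatial axis `axis` of an (x,y,z,C) array
apply_axis_matrix <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:4, axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  a <- matrix(a, nrow = da[1])
  b <- M %*% a
  dim(b) <- c(nrow(M), da[-1])
  aperm(b, order(perm))
}
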