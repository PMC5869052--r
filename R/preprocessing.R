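#' Mean/variance intensity normalization
#'
#' Per channel, shifts and scales intensities so the voxels (inside the mask,
#' if one is given) have mean 0 and variance 1 (population variance).  Voxels
#' outside the mask are transformed with the same affine map, so the operation
#' is a whole-volume intensity change anchored on the masked statistics.
#'
#' @param vol an [image_volume()].
#' @param mask optional binary array of the volume's spatial shape.
#' @return the normalized `image_volume`.
#' @export
meanvar_normalize <- function(vol, mask = NULL) {
  vp_assert(inherits(vol, "image_volume"), "vol must be an image_volume")
  d <- dim(vol$data)
  if (!is.null(mask)) {
    mdim <- dim(mask) %||% length(mask)
    vp_assert(all(mdim[1:3] == d[1:3]), "mask shape does not match volume")
    keep <- as.logical(mask) & !is.na(as.logical(mask))
    vp_assert(any(keep), "mask is empty")
  }
  out <- vol$data
  for (tt in seq_len(d[4])) for (cc in seq_len(d[5])) {
    ch <- vol$data[, , , tt, cc]
    v <- if (is.null(mask)) as.vector(ch) else ch[keep]
    mu <- mean(v)
    sdv <- sqrt(mean((v - mu)^2))
    if (sdv <= .Machine$double.eps * max(1, abs(mu))) {
      vp_stop("zero variance in channel %d ('%s')", cc, vol$modality_names[cc])
    }
    out[, , , tt, cc] <- (ch - mu) / sdv
  }
  vol$data <- out
  vol
}

default_percentiles <- c(1, 5, seq(10, 90, by = 10), 95, 99)

#' Train histogram-standardization landmarks
#'
#' Landmark-based histogram standardization: for every training image the
#' intensities are clipped to the `cutoffs` percentiles, the probed percentile
#' values are rescaled linearly so the endpoints hit the ends of the standard
#' scale, and the rescaled landmark vectors are averaged across the training
#' set, per modality.  The default standard scale maps the percentile ranks
#' linearly onto `[0, 100]`.
#'
#' @param index a `dataset_index` whose `image` section holds the training
#'   images, or a list of `image_volume`s.
#' @param percentiles strictly increasing probe ranks in (0, 100).
#' @param cutoffs `(low_pct, high_pct)` clipping percentiles.
#' @param section section name to train on (default `"image"`).
#' @return a `landmark_model` with fields `percentiles`,
#'   `per_modality_landmarks`, `standard_scale`.
#' @export
train_landmarks <- function(index, percentiles = default_percentiles,
                            cutoffs = c(1, 99), section = "image") {
  vp_assert(all(diff(percentiles) > 0) && all(percentiles > 0 & percentiles < 100),
            "percentiles must be strictly increasing within (0, 100)")
  vols <- if (inherits(index, "dataset_index")) {
    lapply(names(index$subjects), function(s)
      load_volume(index$subjects[[s]][[section]], index$section_specs[[section]]))
  } else index
  vp_assert(length(vols) >= 1, "need at least one training image")
  std <- (percentiles - percentiles[1]) /
         (percentiles[length(percentiles)] - percentiles[1]) * 100
  nmod <- length(vols[[1]]$modality_names)
  marks <- vector("list", nmod)
  for (m in seq_len(nmod)) {
    per_image <- lapply(vols, function(v) {
      x <- as.vector(v$data[, , , , m])
      x <- x[is.finite(x)]
      vp_assert(length(unique(x)) >= length(percentiles),
                "image has fewer distinct finite values than probed percentiles")
      lims <- quantile(x, cutoffs / 100, names = FALSE)
      # clip the landmark values to the cutoff range (equivalent to clipping
      # the intensities, but exact when the cutoffs coincide with the
      # endpoint probe ranks)
      pv <- quantile(x, percentiles / 100, names = FALSE)
      pv <- pmin(pmax(pv, lims[1]), lims[2])
      # linear rescale so the endpoint percentiles hit the standard scale ends
      (pv - pv[1]) / (pv[length(pv)] - pv[1]) *
        (std[length(std)] - std[1]) + std[1]
    })
    marks[[m]] <- Reduce(`+`, per_image) / length(per_image)
  }
  names(marks) <- vols[[1]]$modality_names
  structure(list(percentiles = percentiles,
                 per_modality_landmarks = marks,
                 standard_scale = std),
            class = "landmark_model")
}

#' @export
print.landmark_model <- function(x, ...) {
  cat(sprintf("<landmark_model> %d landmarks, modalities: %s\n",
              length(x$percentiles),
              paste(names(x$per_modality_landmarks), collapse = ", ")))
  invisible(x)
}

# piecewise-linear mapping with linear extrapolation past the end knots;
# knots made strictly increasing by collapsing ties
piecewise_linear_map <- function(x, knots_in, knots_out) {
  keep <- c(TRUE, diff(knots_in) > 0)
  ki <- knots_in[keep]; ko <- knots_out[keep]
  if (length(ki) == 1) return(rep(ko, length(x)) + (x - ki))
  y <- approx(ki, ko, xout = x, rule = 2)$y
  n <- length(ki)
  lo <- x < ki[1]
  hi <- x > ki[n]
  if (any(lo)) y[lo] <- ko[1] + (x[lo] - ki[1]) * (ko[2] - ko[1]) / (ki[2] - ki[1])
  if (any(hi)) y[hi] <- ko[n] + (x[hi] - ki[n]) * (ko[n] - ko[n - 1]) / (ki[n] - ki[n - 1])
  y
}

#' Apply histogram standardization
#'
#' Maps the volume's own percentile values at the model's probe ranks onto the
#' model's standard scale by piecewise-linear interpolation (linear
#' extrapolation beyond the end landmarks).  Because the knots are the
#' volume's own percentiles, the mapping is invariant to affine intensity
#' changes of the input.
#'
#' @param vol an `image_volume`.
#' @param model a `landmark_model` from [train_landmarks()].
#' @return the standardized `image_volume`.
#' @export
histogram_standardize <- function(vol, model) {
  vp_assert(inherits(model, "landmark_model"), "model must be a landmark_model")
  d <- dim(vol$data)
  out <- vol$data
  for (cc in seq_len(d[5])) {
    mod <- vol$modality_names[cc]
    lm <- model$per_modality_landmarks[[mod]]
    if (is.null(lm)) vp_stop("no trained landmarks for modality '%s'", mod)
    ch <- vol$data[, , , , cc]
    own <- quantile(as.vector(ch)[is.finite(as.vector(ch))],
                    model$percentiles / 100, names = FALSE)
    out[, , , , cc] <- array(piecewise_linear_map(as.vector(ch), own, lm), dim = d[1:4])
  }
  vol$data <- out
  vol
}

#' Save or load a landmark model as plain text
#'
#' One header line with the percentile ranks, then one line per modality:
#' the modality name followed by whitespace-separated landmark values.
#'
#' @param model a `landmark_model`.
#' @param path file path.
#' @return `write_landmarks`: the path, invisibly; `read_landmarks`: the
#'   `landmark_model`.
#' @export
write_landmarks <- function(model, path) {
  lines <- c(paste("percentiles", paste(format(model$percentiles, digits = 17), collapse = " ")),
             vapply(names(model$per_modality_landmarks), function(m)
               paste(m, paste(format(model$per_modality_landmarks[[m]], digits = 17),
                              collapse = " ")), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  lines <- readLines(path)
  toks <- strsplit(lines, "\\s+")
  vp_assert(toks[[1]][1] == "percentiles", "malformed landmark file: %s", path)
  pct <- as.numeric(toks[[1]][-1])
  marks <- lapply(toks[-1], function(t) as.numeric(t[-1]))
  names(marks) <- vapply(toks[-1], `[[`, character(1), 1)
  std <- (pct - pct[1]) / (pct[length(pct)] - pct[1]) * 100
  structure(list(percentiles = pct, per_modality_landmarks = marks,
                 standard_scale = std), class = "landmark_model")
}
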