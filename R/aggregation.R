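# Aggregators: recombine per-window network outputs into whole-volume
# outputs (the inverse of grid/resize sampling).

#' Initialize a grid aggregation accumulator
#'
#' @param original_shape spatial shape of the volume being reassembled.
#' @param channels number of output channels (per-class scores for labels).
#' @param border margin of each window discarded on every side.
#' @return an `aggregation_state` (mutable environment) with a float
#'   accumulator, a per-voxel contribution counter and the border record.
#' @export
init_grid_aggregation <- function(original_shape, channels = 1L, border = 0L) {
  os <- as_int3(original_shape, "original shape")
  vp_assert(all(os >= 1), "original shape must be positive")
  vp_assert(channels >= 1, "channels must be positive")
  st <- new.env(parent = emptyenv())
  st$output <- array(0, dim = c(os, channels))
  st$weight <- array(0L, dim = os)
  st$original_shape <- os
  st$border <- as_int3(border, "border")
  st$finalized <- FALSE
  class(st) <- "aggregation_state"
  st
}

#' Accumulate one window's network output
#'
#' Adds the central region of `output_array` (the window shrunk by the
#' state's border) into the accumulator at `start + border`, increments the
#' contribution counter there, and crops away any part that falls outside
#' the original volume (windows from padded volumes).
#'
#' @param state an `aggregation_state`.
#' @param window the `sample_window` the output corresponds to.
#' @param output_array `(x,y,z,channels)` array with the window's spatial
#'   shape (a 3D array is taken as single-channel).
#' @return the state, invisibly (modified in place).
#' @export
accumulate_window <- function(state, window, output_array) {
  vp_assert(inherits(state, "aggregation_state"), "state must be an aggregation_state")
  vp_assert(!state$finalized, "aggregation already finalized")
  if (length(dim(output_array)) == 3) dim(output_array) <- c(dim(output_array), 1L)
  d <- dim(output_array)
  vp_assert(all(d[1:3] == window$shape),
            "output spatial shape (%s) != window shape (%s)",
            paste(d[1:3], collapse = "x"), paste(window$shape, collapse = "x"))
  vp_assert(d[4] == dim(state$output)[4], "channel count mismatch")
  b <- state$border
  # central region in padded-volume coordinates, then shifted to original
  lo <- window$start + b - window$pad_before        # 0-based target start
  hi <- window$start + window$shape - b - window$pad_before  # 0-based exclusive end
  src_lo <- b
  clip_lo <- pmax(0L, -lo)
  clip_hi <- pmax(0L, hi - state$original_shape)
  lo <- lo + clip_lo; hi <- hi - clip_hi
  src_lo <- src_lo + clip_lo
  if (any(hi <= lo)) vp_stop("window central region lies outside the accumulator")
  len <- hi - lo
  ti <- lapply(1:3, function(k) lo[k] + seq_len(len[k]))
  si <- lapply(1:3, function(k) src_lo[k] + seq_len(len[k]))
  state$output[ti[[1]], ti[[2]], ti[[3]], ] <-
    state$output[ti[[1]], ti[[2]], ti[[3]], , drop = FALSE] +
    output_array[si[[1]], si[[2]], si[[3]], , drop = FALSE]
  state$weight[ti[[1]], ti[[2]], ti[[3]]] <-
    state$weight[ti[[1]], ti[[2]], ti[[3]]] + 1L
  invisible(state)
}

#' Finalize an aggregation into a whole-volume result
#'
#' Continuous outputs divide the accumulated scores by the per-voxel
#' contribution count (unweighted averaging of overlapping central regions);
#' label outputs take the argmax over the accumulated per-class score
#' channels, ties broken toward the lower class index (classes are numbered
#' from 0).
#'
#' @param state an `aggregation_state` with every voxel covered at least
#'   once.
#' @param output_kind `"continuous"` or `"label"`.
#' @param reference optional `image_volume` supplying the affine.
#' @return an `image_volume` (label outputs have one channel of class
#'   indices).
#' @export
finalize_aggregation <- function(state, output_kind = c("continuous", "label"),
                                 reference = NULL) {
  output_kind <- match.arg(output_kind)
  vp_assert(!state$finalized, "aggregation already finalized")
  if (any(state$weight < 1L)) {
    vp_stop("incomplete coverage: %d voxel(s) received no contribution",
            sum(state$weight < 1L))
  }
  nc <- dim(state$output)[4]
  if (output_kind == "continuous") {
    out <- state$output / as.vector(state$weight)  # weight recycles over channels
  } else {
    out <- array(max.col(matrix(state$output, ncol = nc), ties.method = "first") - 1,
                 dim = c(state$original_shape, 1L))
  }
  state$finalized <- TRUE
  aff <- if (!is.null(reference)) reference$affine else diag(4)
  image_volume(out, affine = aff,
               section = if (output_kind == "label") "label" else "inferred")
}

#' Invert a resize sampling
#'
#' Rescales a window output produced from [resize_sample()] back to the
#' original volume shape (nearest-neighbour for labels, trilinear for
#' continuous outputs).
#'
#' @param window_output `(x,y,z,channels)` array (or 3D array).
#' @param original_shape the shape recorded by the resize sampler.
#' @param output_kind `"continuous"` or `"label"`; label outputs of more
#'   than one channel are argmaxed before resizing.
#' @param reference optional `image_volume` supplying the affine.
#' @return an `image_volume` at `original_shape`.
#' @export
resize_aggregate <- function(window_output, original_shape,
                             output_kind = c("continuous", "label"),
                             reference = NULL) {
  output_kind <- match.arg(output_kind)
  if (length(dim(window_output)) == 3) dim(window_output) <- c(dim(window_output), 1L)
  os <- as_int3(original_shape, "original shape")
  nc <- dim(window_output)[4]
  if (output_kind == "label") {
    if (nc > 1) {
      window_output <- array(
        max.col(matrix(window_output, ncol = nc), ties.method = "first") - 1,
        dim = c(dim(window_output)[1:3], 1L))
    }
    out <- resize_array(window_output, os, "nearest")
  } else {
    out <- resize_array(window_output, os, "linear")
  }
  aff <- if (!is.null(reference)) reference$affine else diag(4)
  image_volume(out, affine = aff,
               section = if (output_kind == "label") "label" else "inferred")
}
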