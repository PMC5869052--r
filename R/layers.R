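# Composable named-scope network blocks.  Every block registers its
# parameters in a vx_param_store under a hierarchical name; calling a block
# again with the same store and name reuses the same parameters.

#' Convolution block: convolution, normalization, activation
#'
#' Stride-1, zero-padded (shape-preserving) 3D convolution followed by
#' batch-independent layer normalization (over the channel axis, per voxel)
#' and a pointwise activation.
#' Parameters are registered under `name/conv/{weight,bias}` and
#' `name/norm/{gamma,beta}`; invoking the block twice with the same name
#' shares them.
#'
#' @param store a [vx_param_store()].
#' @param tape a `vx_tape` (internal autodiff recorder).
#' @param x input node with value of shape `(x, y, z, channels)`.
#' @param out_channels number of output channels.
#' @param kernel odd kernel size (scalar or 3 ints).
#' @param activation `"relu"` or `"linear"`.
#' @param name hierarchical scope name.
#' @param norm apply instance normalization (disable for plain projections).
#' @return the output node, same spatial shape as the input.
#' @export
conv_block <- function(store, tape, x, out_channels, kernel = 3,
                       activation = c("relu", "linear"), name, norm = TRUE) {
  activation <- match.arg(activation)
  k <- as_int3(kernel, "kernel")
  vp_assert(all(k %% 2 == 1), "kernel sizes must be odd")
  d <- dim(x$value)
  vp_assert(length(d) == 4, "conv_block input must have a channel axis")
  vp_assert(all(k <= d[1:3] + (k - 1L)), "kernel larger than padded input")
  cin <- d[4]
  w <- vx_param(store, tape, paste0(name, "/conv/weight"),
                c(k, cin, out_channels), "he", fan_in = prod(k) * cin)
  b <- vx_param(store, tape, paste0(name, "/conv/bias"), out_channels, "zeros")
  h <- op_conv3d(tape, x, w, b)
  if (norm) {
    gamma <- vx_param(store, tape, paste0(name, "/norm/gamma"), out_channels, "ones")
    beta <- vx_param(store, tape, paste0(name, "/norm/beta"), out_channels, "zeros")
    h <- op_layer_norm(tape, h, gamma, beta)
  }
  if (activation == "relu") h <- op_relu(tape, h) else h
}

#' Dense feature stack
#'
#' A sequence of convolution blocks where block i consumes the channel
#' concatenation of the stack input and the outputs of blocks 1..i-1, and the
#' stack returns the concatenation of all block outputs.  With `C0` input
#' channels, block i sees `C0 + (i-1) * growth_channels` input channels and
#' the stack returns `n_blocks * growth_channels` channels.
#'
#' @inheritParams conv_block
#' @param n_blocks number of blocks (>= 1).
#' @param growth_channels output channels of each block.
#' @return the concatenated output node.
#' @export
dense_feature_stack <- function(store, tape, x, n_blocks, growth_channels,
                                name, kernel = 3) {
  vp_assert(n_blocks >= 1, "n_blocks must be >= 1")
  feats <- list()
  for (i in seq_len(n_blocks)) {
    xin <- if (i == 1) x else op_concat(tape, c(list(x), feats))
    feats[[i]] <- conv_block(store, tape, xin, growth_channels, kernel,
                             "relu", sprintf("%s/block%d", name, i))
  }
  op_concat(tape, feats)
}

#' Reference V-shaped segmentation network
#'
#' A small V-shaped network built from dense feature stacks: per level a
#' dense feature stack followed by 2x average-pool downsampling; trilinear 2x
#' upsampling on the way back up, with each level's stack output projected by
#' a 1x1x1 convolution (the skip connection) and summed into the upsampled
#' path; then a 3x3x3 head block and a final 1x1x1 convolution to per-class
#' score channels.  Spatial dims must be divisible by `2^depth`.
#'
#' The default (depth 2, growth 8) is a deliberately small model — tens of
#' thousands of parameters — trainable on one CPU in minutes.
#'
#' @param in_channels input channels.
#' @param n_classes number of output classes (score channels).
#' @param config list with optional `depth` (number of downsamplings,
#'   default 2), `growth` (channels per dense block, default 8), `n_blocks`
#'   (blocks per stack, default 2), `scope` (root parameter scope, default
#'   `"net"`).
#' @return a `vx_network`: list with `name` and
#'   `forward(store, tape, x_node)`.
#' @export
build_reference_segnet <- function(in_channels, n_classes, config = list()) {
  depth <- config$depth %||% 2L
  growth <- config$growth %||% 8L
  n_blocks <- config$n_blocks %||% 2L
  root <- config$scope %||% "net"
  sc <- n_blocks * growth  # channels out of every stack
  forward <- function(store, tape, x) {
    d <- dim(x$value)
    vp_assert(all(d[1:3] %% (2^depth) == 0),
              "spatial shape (%s) not divisible by 2^depth = %d",
              paste(d[1:3], collapse = "x"), 2^depth)
    stacks <- vector("list", depth + 1)
    h <- x
    for (l in 0:depth) {
      if (l > 0) h <- op_avgpool2(tape, h)
      h <- dense_feature_stack(store, tape, h, n_blocks, growth,
                               sprintf("%s/level%d/dfs", root, l))
      stacks[[l + 1]] <- h
    }
    u <- stacks[[depth + 1]]
    for (l in seq.int(depth - 1, 0)) {
      u <- op_upsample2(tape, u)
      skip <- conv_block(store, tape, stacks[[l + 1]], sc, 1, "linear",
                         sprintf("%s/level%d/skip", root, l), norm = FALSE)
      u <- op_add(tape, u, skip)
    }
    h <- conv_block(store, tape, u, growth, 3, "relu", paste0(root, "/head"))
    conv_block(store, tape, h, n_classes, 1, "linear", paste0(root, "/out"),
               norm = FALSE)
  }
  structure(list(name = root, in_channels = in_channels, n_classes = n_classes,
                 depth = depth, growth = growth, n_blocks = n_blocks,
                 out_channels = n_classes, forward = forward),
            class = "vx_network")
}

#' Identity network
#'
#' Passes its input through unchanged; used to exercise the
#' sampler/aggregator round trip end to end.
#'
#' @param in_channels input channels (also the output channels).
#' @param n_classes ignored; present for factory-signature compatibility.
#' @param config ignored.
#' @return a `vx_network`.
#' @export
build_identity_network <- function(in_channels = 1L, n_classes = NULL,
                                   config = list()) {
  structure(list(name = "identity", in_channels = in_channels,
                 n_classes = n_classes, out_channels = in_channels,
                 forward = function(store, tape, x) x),
            class = "vx_network")
}

#' @export
print.vx_network <- function(x, ...) {
  cat(sprintf("<vx_network> %s\n", x$name))
  invisible(x)
}

#' Soft multi-class Dice loss
#'
#' Per class c, with one-hot ground truth g and predicted probabilities p,
#' `d_c = (2 * sum(p_c g_c) + eps) / (sum(p_c) + sum(g_c) + eps)`; the loss
#' is `1 - mean_c(d_c)`, in `[0, 1]`.  The mean runs over all classes
#' including background.
#'
#' @param pred_probs `(x, y, z, n_classes)` array of class probabilities
#'   (summing to 1 over the class axis).
#' @param labels integer array of true labels in `[0, n_classes)`.
#' @param n_classes number of classes.
#' @param eps stabilizer (default 1e-5).
#' @return scalar loss.
#' @export
soft_dice_loss <- function(pred_probs, labels, n_classes, eps = 1e-5) {
  d <- dim(pred_probs)
  vp_assert(d[length(d)] == n_classes, "last axis must have n_classes channels")
  lab <- as.integer(round(as.vector(labels)))
  if (any(lab < 0 | lab >= n_classes)) vp_stop("label values outside [0, %d)", n_classes)
  nvox <- prod(d[-length(d)])
  p <- matrix(pred_probs, nrow = nvox)
  G <- matrix(0, nvox, n_classes)
  G[cbind(seq_len(nvox), lab + 1L)] <- 1
  dice <- (2 * colSums(p * G) + eps) / (colSums(p) + colSums(G) + eps)
  1 - mean(dice)
}

#' Root-mean-square error loss
#'
#' @param pred,target arrays of equal shape.
#' @param mask optional logical/binary array; the error is computed over
#'   masked voxels only.
#' @return scalar RMSE.
#' @export
rmse_loss <- function(pred, target, mask = NULL) {
  vp_assert(length(pred) == length(target), "pred and target shapes differ")
  r <- pred - target
  if (!is.null(mask)) {
    keep <- as.logical(mask)
    vp_assert(any(keep), "empty mask")
    r <- r[keep]
  }
  sqrt(mean(r^2))
}

# run a network forward on a plain (x,y,z,C) array, returning the value
network_forward <- function(network, store, arr) {
  tape <- vx_tape()
  x <- vx_const(tape, arr)
  out <- network$forward(store, tape, x)
  out$value
}

# softmax over the channel axis of an (x,y,z,C) array
softmax_channels <- function(arr) {
  d <- dim(arr)
  z <- matrix(arr, ncol = d[4])
  z <- z - apply(z, 1, max)
  e <- exp(z)
  array(e / rowSums(e), dim = d)
}
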