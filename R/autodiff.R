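# Minimal reverse-mode automatic differentiation tape.
#
# A vx_tape records operation nodes in creation order (a valid topological
# order); vx_backward() walks it in reverse, each node's backfn mapping the
# upstream gradient to gradients for its parents.  Values are plain R arrays;
# the heavy 3D convolution kernels are in C++ (src/ops.cpp).  Parameter leaf
# nodes carry the hierarchical scope name under which the parameter lives in
# a vx_param_store, giving named-scope weight sharing, checkpointing and
# scope-renamed restores.

vx_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 64L)
  e$n <- 0L
  class(e) <- "vx_tape"
  e
}

vx_node <- function(tape, value, parents = list(), backfn = NULL, scope = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$scope <- scope
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
    tape$nodes[[tape$n]] <- nd
  }
  class(nd) <- "vx_node"
  nd
}

vx_const <- function(tape, value) vx_node(tape, value)

vx_value <- function(node) node$value

# reverse pass: seed the root with gradient 1 and accumulate into parents
vx_backward <- function(tape, root) {
  root$grad <- if (length(root$value) == 1L) 1 else array(1, dim = dim(root$value))
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- nd$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(tape)
}

# gradients of all parameter leaves on a tape, summed per scope
tape_param_grads <- function(tape) {
  out <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$scope) || is.null(nd$grad)) next
    out[[nd$scope]] <- if (is.null(out[[nd$scope]])) nd$grad else out[[nd$scope]] + nd$grad
  }
  out
}

## ---- elementwise and structural ops ----------------------------------------

op_add <- function(tape, a, b) {
  vx_node(tape, a$value + b$value, list(a, b),
          function(g) list(g, g))
}

op_relu <- function(tape, x) {
  pos <- x$value > 0
  vx_node(tape, x$value * pos, list(x),
          function(g) list(g * pos))
}

op_concat <- function(tape, nodes) {
  if (length(nodes) == 1L) return(nodes[[1]])
  dims <- lapply(nodes, function(n) dim(n$value))
  ch <- vapply(dims, function(d) d[4], numeric(1))
  sp <- dims[[1]][1:3]
  val <- array(0, dim = c(sp, sum(ch)))
  at <- 0
  for (k in seq_along(nodes)) {
    val[, , , at + seq_len(ch[k])] <- nodes[[k]]$value
    at <- at + ch[k]
  }
  vx_node(tape, val, nodes, function(g) {
    out <- vector("list", length(nodes))
    at <- 0
    for (k in seq_along(nodes)) {
      out[[k]] <- g[, , , at + seq_len(ch[k]), drop = FALSE]
      at <- at + ch[k]
    }
    out
  })
}

## ---- convolution ------------------------------------------------------------

op_conv3d <- function(tape, x, w, b = NULL) {
  xd <- dim(x$value)
  wd <- dim(w$value)
  y <- cpp_conv3d_fwd(as.vector(x$value), as.integer(xd),
                      as.vector(w$value), as.integer(wd))
  nvox <- prod(xd[1:3])
  if (!is.null(b)) y <- y + rep(b$value, each = nvox)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  vx_node(tape, y, parents, function(g) {
    gx <- cpp_conv3d_bwd_input(as.vector(g), as.integer(xd),
                               as.vector(w$value), as.integer(wd))
    gw <- cpp_conv3d_bwd_weight(as.vector(x$value), as.integer(xd),
                                as.vector(g), as.integer(wd))
    if (is.null(b)) list(gx, gw)
    else list(gx, gw, colSums(matrix(g, nrow = nvox)))
  })
}

## ---- normalization ----------------------------------------------------------

# layer normalization over the channel axis, per voxel: batch-independent
# (suitable for batch size 1) and, unlike per-window instance statistics,
# preserves absolute intensity differences between windows
op_layer_norm <- function(tape, x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  nvox <- prod(d[1:3])
  nc <- d[4]
  xm <- matrix(x$value, nrow = nvox)
  mu <- rowMeans(xm)
  va <- rowMeans(xm^2) - mu^2
  invstd <- 1 / sqrt(pmax(va, 0) + eps)
  xhat <- (xm - mu) * invstd
  y <- sweep(sweep(xhat, 2, gamma$value, `*`), 2, beta$value, `+`)
  vx_node(tape, array(y, dim = d), list(x, gamma, beta), function(g) {
    gm <- matrix(g, nrow = nvox)
    dxhat <- sweep(gm, 2, gamma$value, `*`)
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    dx <- (dxhat - m1 - xhat * m2) * invstd
    list(array(dx, dim = d), colSums(gm * xhat), colSums(gm))
  })
}

op_instance_norm <- function(tape, x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  nvox <- prod(d[1:3])
  xm <- matrix(x$value, nrow = nvox)
  mu <- colMeans(xm)
  va <- colMeans(xm^2) - mu^2
  invstd <- 1 / sqrt(pmax(va, 0) + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, invstd, `*`)
  y <- sweep(sweep(xhat, 2, gamma$value, `*`), 2, beta$value, `+`)
  vx_node(tape, array(y, dim = d), list(x, gamma, beta), function(g) {
    gm <- matrix(g, nrow = nvox)
    dxhat <- sweep(gm, 2, gamma$value, `*`)
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, `*`)
    dx <- sweep(dx, 2, invstd, `*`)
    list(array(dx, dim = d), colSums(gm * xhat), colSums(gm))
  })
}

## ---- pooling / upsampling ---------------------------------------------------

op_avgpool2 <- function(tape, x) {
  d <- dim(x$value)
  vp_assert(all(d[1:3] %% 2 == 0), "avgpool2 needs even spatial dims, got %s",
            paste(d[1:3], collapse = "x"))
  h <- d[1:3] %/% 2L
  a <- array(x$value, c(2L, h[1], 2L, h[2], 2L, h[3], d[4]))
  a <- aperm(a, c(1, 3, 5, 2, 4, 6, 7))
  y <- array(colMeans(matrix(a, nrow = 8L)), c(h, d[4]))
  vx_node(tape, y, list(x), function(g) {
    b <- array(rep(as.vector(g) / 8, each = 8L), c(2L, 2L, 2L, h, d[4]))
    b <- aperm(b, c(1, 4, 2, 5, 3, 6, 7))
    list(array(b, dim = d))
  })
}

.upsample_cache <- new.env(parent = emptyenv())

upsample2_matrix_cached <- function(n) {
  key <- as.character(n)
  if (is.null(.upsample_cache[[key]])) .upsample_cache[[key]] <- upsample2_matrix(n)
  .upsample_cache[[key]]
}

# factor-2 trilinear upsampling (separable); backward is the exact adjoint
op_upsample2 <- function(tape, x) {
  d <- dim(x$value)
  U <- lapply(1:3, function(k) upsample2_matrix_cached(d[k]))
  y <- apply_axis_matrix(x$value, U[[1]], 1)
  y <- apply_axis_matrix(y, U[[2]], 2)
  y <- apply_axis_matrix(y, U[[3]], 3)
  vx_node(tape, y, list(x), function(g) {
    gx <- apply_axis_matrix(g, t(U[[3]]), 3)
    gx <- apply_axis_matrix(gx, t(U[[2]]), 2)
    gx <- apply_axis_matrix(gx, t(U[[1]]), 1)
    list(gx)
  })
}

## ---- losses (fused, with analytic gradients) -------------------------------

# softmax over the channel axis followed by soft multi-class Dice loss
op_softmax_dice <- function(tape, logits, labels, n_classes, eps = 1e-5) {
  d <- dim(logits$value)
  nc <- d[4]
  vp_assert(nc == n_classes, "logit channels (%d) != n_classes (%d)", nc, n_classes)
  lab <- as.integer(round(as.vector(labels)))
  if (any(lab < 0 | lab >= n_classes)) {
    vp_stop("label values outside [0, %d)", n_classes)
  }
  nvox <- prod(d[1:3])
  z <- matrix(logits$value, nrow = nvox)
  z <- z - apply(z, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  G <- matrix(0, nvox, nc)
  G[cbind(seq_len(nvox), lab + 1L)] <- 1
  A <- 2 * colSums(p * G) + eps
  B <- colSums(p) + colSums(G) + eps
  loss <- 1 - mean(A / B)
  vx_node(tape, loss, list(logits), function(g) {
    dLdp <- -(sweep(2 * G, 2, B, `*`) - matrix(A, nvox, nc, byrow = TRUE))
    dLdp <- sweep(dLdp, 2, nc * B^2, `/`)
    dz <- p * (dLdp - rowSums(dLdp * p))
    list(array(g * dz, dim = d))
  })
}

# root-mean-square error over (optionally masked) voxels
op_rmse <- function(tape, pred, target, mask = NULL) {
  r <- pred$value - target
  if (!is.null(mask)) {
    keep <- as.logical(mask)
    vp_assert(any(keep), "empty mask in rmse loss")
  } else keep <- NULL
  rv <- if (is.null(keep)) as.vector(r) else r[keep]
  n <- length(rv)
  L <- sqrt(mean(rv^2))
  vx_node(tape, L, list(pred), function(g) {
    gr <- array(0, dim = dim(r) %||% length(r))
    core <- if (L > 0) rv / (n * L) else rv * 0
    if (is.null(keep)) gr[] <- core else gr[keep] <- core
    list(g * gr)
  })
}

# mean binary cross-entropy on logits
op_sigmoid_bce <- function(tape, logits, targets) {
  z <- logits$value
  t <- targets
  val <- mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
  n <- length(z)
  vx_node(tape, val, list(logits), function(g) {
    list(g * (1 / (1 + exp(-z)) - t) / n)
  })
}

# y = w * x + c with scalar parameters (logistic-regression style layers)
op_scale_shift <- function(tape, x, w, c) {
  vx_node(tape, w$value[1] * x$value + c$value[1], list(x, w, c), function(g) {
    list(g * w$value[1], sum(g * x$value), sum(g))
  })
}

# mean of scalar nodes (mini-batch loss averaging)
op_mean_list <- function(tape, nodes) {
  if (length(nodes) == 1L) return(nodes[[1]])
  n <- length(nodes)
  vx_node(tape, mean(vapply(nodes, function(x) x$value, numeric(1))), nodes,
          function(g) rep(list(g / n), n))
}

# y = x + b (scalar parameter broadcast)
op_add_scalar <- function(tape, x, b) {
  vx_node(tape, x$value + b$value[1], list(x, b), function(g) {
    list(g, sum(g))
  })
}

## ---- parameter store and optimizer ------------------------------------------

#' Parameter store with hierarchically named scopes
#'
#' Holds every trainable parameter of a network under its scope string (e.g.
#' `"net/level0/dfs/block1/conv/weight"`).  Re-invoking a layer with the same
#' name reuses the stored array, which is what makes named blocks shareable
#' and restorable.  Initialization draws from the store's own RNG stream, so
#' networks are reproducible per seed.
#'
#' @param init_rng an [rng_stream()] used for weight initialization.
#' @return a `vx_param_store`.
#' @export
vx_param_store <- function(init_rng = rng_stream(1)) {
  e <- new.env(parent = emptyenv())
  e$params <- new.env(parent = emptyenv())
  e$order <- character(0)
  e$rng <- init_rng
  class(e) <- "vx_param_store"
  e
}

#' @export
print.vx_param_store <- function(x, ...) {
  n <- vapply(x$order, function(s) length(x$params[[s]]), numeric(1))
  cat(sprintf("<vx_param_store> %d parameter array(s), %d values\n",
              length(x$order), sum(n)))
  invisible(x)
}

# fetch-or-create a parameter, returning its tape leaf node
vx_param <- function(store, tape, scope, shape, init = "he", fan_in = NULL) {
  if (is.null(store$params[[scope]])) {
    val <- switch(init,
      he = with_rng(store$rng,
        array(rnorm(prod(shape), 0, sqrt(2 / (fan_in %||% prod(shape)))), dim = shape)),
      zeros = array(0, dim = shape),
      ones = array(1, dim = shape))
    store$params[[scope]] <- val
    store$order <- c(store$order, scope)
  } else {
    vp_assert(all(dim(store$params[[scope]]) == shape),
              "scope '%s' exists with different shape", scope)
  }
  vx_node(tape, store$params[[scope]], scope = scope)
}

# number of parameter arrays in a store
n_parameters <- function(store) length(store$order)

#' Adam optimizer over a parameter store
#'
#' @param store a [vx_param_store()].
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param scopes optional character vector of scope prefixes; when given,
#'   only parameters whose scope starts with one of them are updated
#'   (used for the alternating generator/discriminator steps).
#' @return a `vx_adam` optimizer object.
#' @export
vx_adam <- function(store, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                    scopes = NULL) {
  e <- new.env(parent = emptyenv())
  e$store <- store; e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$scopes <- scopes
  e$t <- 0L
  e$m <- new.env(parent = emptyenv())
  e$v <- new.env(parent = emptyenv())
  class(e) <- "vx_adam"
  e
}

scope_matches <- function(scope, prefixes) {
  if (is.null(prefixes)) return(TRUE)
  any(vapply(prefixes, function(p) startsWith(scope, p), logical(1)))
}

#' One Adam update from the gradients recorded on a tape
#'
#' @param opt a [vx_adam()] optimizer.
#' @param tape a backward-passed `vx_tape`.
#' @return the optimizer, invisibly.
#' @export
vx_adam_step <- function(opt, tape) {
  grads <- tape_param_grads(tape)
  grads <- grads[vapply(names(grads), scope_matches, logical(1), opt$scopes)]
  if (length(grads) == 0) return(invisible(opt))
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (s in names(grads)) {
    g <- grads[[s]]
    m <- opt$m[[s]] %||% (g * 0)
    v <- opt$v[[s]] %||% (g * 0)
    m <- opt$beta1 * m + (1 - opt$beta1) * g
    v <- opt$beta2 * v + (1 - opt$beta2) * g^2
    opt$m[[s]] <- m
    opt$v[[s]] <- v
    opt$store$params[[s]] <- opt$store$params[[s]] -
      opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps)
  }
  invisible(opt)
}
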