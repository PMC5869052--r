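test_that("conv_block preserves shape, supports identity weights, shares scopes", {
  store <- vx_param_store(rng_stream(1))
  tape <- vx$vx_tape()
  set.seed(17)
  x <- vx$vx_const(tape, array(rnorm(4^3 * 2), c(4, 4, 4, 2)))

  out <- conv_block(store, tape, x, 3, kernel = 3, name = "blk")
  expect_equal(dim(out$value), c(4L, 4L, 4L, 3L))

  n1 <- vx$n_parameters(store)
  out2 <- conv_block(store, tape, x, 3, kernel = 3, name = "blk")
  expect_equal(vx$n_parameters(store), n1)       # scope reuse: no new params
  expect_identical(out$value, out2$value)

  # identity-initialized 1x1x1 kernel, no norm, linear activation
  store2 <- vx_param_store(rng_stream(1))
  t2 <- vx$vx_tape()
  conv_block(store2, t2, x, 2, kernel = 1, activation = "linear",
             name = "id", norm = FALSE)
  w <- array(0, c(1, 1, 1, 2, 2)); w[1, 1, 1, 1, 1] <- 1; w[1, 1, 1, 2, 2] <- 1
  store2$params[["id/conv/weight"]] <- w
  t3 <- vx$vx_tape()
  out3 <- conv_block(store2, t3, x, 2, kernel = 1, activation = "linear",
                     name = "id", norm = FALSE)
  expect_equal(out3$value, x$value)

  expect_error(conv_block(store, tape, x, 2, kernel = 2, name = "even"), "odd")
})

test_that("dense feature stack concatenates per the channel arithmetic", {
  store <- vx_param_store(rng_stream(2))
  tape <- vx$vx_tape()
  x <- vx$vx_const(tape, array(rnorm(4^3 * 4), c(4, 4, 4, 4)))
  out <- dense_feature_stack(store, tape, x, n_blocks = 3, growth_channels = 8,
                             name = "dfs")
  expect_equal(dim(out$value)[4], 24L)
  # block input channel counts 4, 12, 20 visible in the stored kernel shapes
  for (i in 1:3) {
    w <- store$params[[sprintf("dfs/block%d/conv/weight", i)]]
    expect_equal(dim(w)[4], c(4L, 12L, 20L)[i])
  }
  # n_blocks = 1 degenerates to a single conv block
  store3 <- vx_param_store(rng_stream(2))
  t3 <- vx$vx_tape()
  one <- dense_feature_stack(store3, t3, x, 1, 8, name = "dfs")
  expect_equal(dim(one$value)[4], 8L)
  expect_equal(vx$n_parameters(store3), 4L)  # weight, bias, gamma, beta

  # channel-count formula over a grid of configurations
  for (cfg in list(c(1, 4, 2), c(3, 2, 4), c(2, 8, 1))) {
    s <- vx_param_store(rng_stream(3)); t <- vx$vx_tape()
    xin <- vx$vx_const(t, array(0, c(2, 2, 2, cfg[1])))
    o <- dense_feature_stack(s, t, xin, cfg[3], cfg[2], name = "g")
    expect_equal(dim(o$value)[4], cfg[3] * cfg[2])
  }
})

test_that("gradients flow to the first dense block (finite differences)", {
  store <- vx_param_store(rng_stream(4))
  set.seed(18)
  x <- array(rnorm(2 * 2 * 2 * 2), c(2, 2, 2, 2))
  run <- function() {
    tape <- vx$vx_tape()
    out <- dense_feature_stack(store, tape, vx$vx_const(tape, x), 3, 2, name = "d")
    target <- array(1, dim(out$value))
    loss <- vx$op_rmse(tape, out, target)
    list(tape = tape, loss = loss)
  }
  r <- run()
  vx$vx_backward(r$tape, r$loss)
  g <- vx$tape_param_grads(r$tape)[["d/block1/conv/weight"]]
  expect_false(is.null(g))
  i <- which.max(abs(g))
  p0 <- store$params[["d/block1/conv/weight"]][i]
  eps <- 1e-6
  store$params[["d/block1/conv/weight"]][i] <- p0 + eps
  lp <- run()$loss$value
  store$params[["d/block1/conv/weight"]][i] <- p0 - eps
  lm <- run()$loss$value
  store$params[["d/block1/conv/weight"]][i] <- p0
  fd <- (lp - lm) / (2 * eps)
  expect_lt(abs(g[i] - fd), 1e-6 * max(1, abs(fd)))
})

test_that("reference segnet meets its shape, scope and determinism contracts", {
  net <- build_reference_segnet(1, 4, list(depth = 2, growth = 4))
  store <- vx_param_store(rng_stream(5))
  set.seed(19)
  x <- array(rnorm(8^3), c(8, 8, 8, 1))
  o1 <- vx$network_forward(net, store, x)
  expect_equal(dim(o1), c(8L, 8L, 8L, 4L))
  o2 <- vx$network_forward(net, store, x)
  expect_identical(o1, o2)  # deterministic forward

  # one parameter subtree per level
  scopes <- store$order
  for (l in 0:2) expect_true(any(startsWith(scopes, sprintf("net/level%d/", l))))

  bad <- array(0, c(6, 6, 6, 1))  # not divisible by 2^depth
  expect_error(vx$network_forward(net, store, bad), "divisible")
})

test_that("checkpoints restore forward outputs bitwise, with scope renames", {
  net <- build_reference_segnet(1, 2, list(depth = 1, growth = 4))
  store <- vx_param_store(rng_stream(6))
  set.seed(20)
  x <- array(rnorm(4^3), c(4, 4, 4, 1))
  o1 <- vx$network_forward(net, store, x)
  dir <- tempfile("ck")
  save_checkpoint(store, 5, NULL, dir)

  fresh <- vx_param_store(rng_stream(99))
  apply_checkpoint(fresh, restore_checkpoint(dir))
  expect_identical(vx$network_forward(net, fresh, x), o1)

  # renamed restore transplants a block's weights verbatim
  ck <- restore_checkpoint(dir, scope_renames = c("net/level0" = "net2/encoder"))
  expect_true(any(startsWith(names(ck$parameter_map), "net2/encoder/")))
  tr <- vx_param_store(rng_stream(100))
  apply_checkpoint(tr, ck)
  t1 <- vx$vx_tape()
  xin <- vx$vx_const(t1, x)
  a <- dense_feature_stack(store, t1, xin, 2, 4, name = "net/level0/dfs")
  t2 <- vx$vx_tape()
  b <- dense_feature_stack(tr, t2, vx$vx_const(t2, x), 2, 4, name = "net2/encoder/dfs")
  expect_identical(a$value, b$value)

  # wrong shape on restore errors naming the scope
  wrong <- vx_param_store(rng_stream(7))
  t3 <- vx$vx_tape()
  dense_feature_stack(wrong, t3, vx$vx_const(t3, array(0, c(4, 4, 4, 2))),
                      2, 4, name = "net/level0/dfs")
  expect_error(apply_checkpoint(wrong, restore_checkpoint(dir)),
               "shape mismatch.*net/level0")
  expect_error(restore_checkpoint(dir, scope_renames = c("nope" = "x")),
               "unmatched scope")
})

test_that("layer normalization and pooling gradients match finite differences", {
  store <- vx_param_store(rng_stream(8))
  set.seed(21)
  x <- array(rnorm(4^3 * 2), c(4, 4, 4, 2))
  run <- function(xv) {
    tape <- vx$vx_tape()
    xn <- vx$vx_const(tape, xv)
    h <- conv_block(store, tape, xn, 2, name = "cb")
    h <- vx$op_avgpool2(tape, h)
    h <- vx$op_upsample2(tape, h)
    loss <- vx$op_rmse(tape, h, array(0.3, dim(h$value)))
    list(tape = tape, loss = loss, xn = xn)
  }
  r <- run(x)
  vx$vx_backward(r$tape, r$loss)
  gi <- r$xn$grad
  i <- which.max(abs(gi))
  eps <- 1e-6
  x2 <- x; x2[i] <- x[i] + eps; lp <- run(x2)$loss$value
  x2[i] <- x[i] - eps; lm <- run(x2)$loss$value
  fd <- (lp - lm) / (2 * eps)
  expect_lt(abs(gi[i] - fd), 1e-5 * max(1, abs(fd)))
})
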