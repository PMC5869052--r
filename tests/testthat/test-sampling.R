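make_vols <- function(shape = c(5, 4, 4), seed = 1) {
  set.seed(seed)
  list(image = array(rnorm(prod(shape)), c(shape, 1)),
       label = array(sample(0:1, prod(shape), TRUE), c(shape, 1)))
}

test_that("uniform sampler draws valid, seed-deterministic starts", {
  vols <- make_vols()
  # window == volume: single valid position
  w <- uniform_sample(vols, c(5, 4, 4), 5, rng_stream(1))
  expect_true(all(vapply(w, function(x) all(x$start == 0L), logical(1))))

  # 5x4x4 volume, 4^3 window: starts in {(0,0,0),(1,0,0)}, about half each
  draws <- uniform_sample(vols, c(4, 4, 4), 2000, rng_stream(2))
  xs <- vapply(draws, function(d) d$start[1], integer(1))
  expect_true(all(xs %in% c(0L, 1L)))
  expect_true(all(vapply(draws, function(d) all(d$start[2:3] == 0L), logical(1))))
  expect_lt(abs(sum(xs == 0) - 1000), 100)  # binomial 99% bound

  s1 <- uniform_sample(vols, c(3, 3, 3), 10, rng_stream(7))
  s2 <- uniform_sample(vols, c(3, 3, 3), 10, rng_stream(7))
  expect_identical(lapply(s1, `[[`, "start"), lapply(s2, `[[`, "start"))

  expect_error(uniform_sample(vols, c(9, 4, 4), 1, rng_stream(1), pad = FALSE),
               "padding disabled")
})

test_that("all samplers crop every section with the same start", {
  # coordinate-valued volume: cropped values reveal the crop origin
  shape <- c(6, 6, 6)
  coords <- vx$coord_grid(shape)
  cvol <- array(coords[, 1] + 10 * coords[, 2] + 100 * coords[, 3], c(shape, 1))
  vols <- list(image = cvol, label = cvol)
  for (w in c(uniform_sample(vols, c(3, 3, 3), 4, rng_stream(1)),
              grid_sample(vols, c(3, 3, 3)))) {
    expect_identical(w$arrays$image, w$arrays$label)
    expect_equal(w$arrays$image[1, 1, 1, 1],
                 w$start[1] + 10 * w$start[2] + 100 * w$start[3])
  }
})

test_that("weighted sampler follows the weight map over window centres", {
  shape <- c(5, 4, 4)
  img <- array(0, c(shape, 1))
  # delta weight: every sample centred on that voxel
  wmap <- array(0, c(shape, 1)); wmap[3, 2, 2, 1] <- 1
  vols <- list(image = img, weight = wmap)
  draws <- weighted_sample(vols, c(3, 3, 3), "weight", 20, rng_stream(1))
  for (d in draws) expect_equal(d$start + c(3, 3, 3) %/% 2L, c(2L, 1L, 1L))

  # two valid centres with weights 1 and 3: frequencies ~ 0.25 / 0.75
  w2 <- array(0, c(shape, 1))
  w2[2, 2, 2, 1] <- 1; w2[3, 2, 2, 1] <- 3
  draws <- weighted_sample(list(image = img, weight = w2), c(3, 3, 3),
                           "weight", 4000, rng_stream(2))
  f <- mean(vapply(draws, function(d) d$start[1] == 1L, logical(1)))
  expect_lt(abs(f - 0.75), 0.03)

  expect_error(weighted_sample(list(image = img, weight = img), c(3, 3, 3),
                               "weight", 1, rng_stream(1)), "all-zero")
})

test_that("uniform and weighted samplers pass chi-square against their laws", {
  shape <- c(5, 4, 4)  # 2 x 1 x 1 valid positions for a 4^3 window
  vols <- make_vols(shape)
  xs <- vapply(uniform_sample(vols, c(4, 4, 4), 4000, rng_stream(3)),
               function(d) d$start[1], integer(1))
  expect_gt(chisq.test(table(factor(xs, 0:1)))$p.value, 0.001)

  # uniform weights reproduce the uniform law
  wmap <- array(1, c(shape, 1))
  xs2 <- vapply(weighted_sample(list(image = vols$image, weight = wmap),
                                c(4, 4, 4), "weight", 4000, rng_stream(4)),
                function(d) d$start[1], integer(1))
  expect_gt(chisq.test(table(factor(xs2, 0:1)))$p.value, 0.001)
})

test_that("grid sampler tiles per the stated start rule in (x,y,z) order", {
  vols <- make_vols(c(8, 8, 8))
  g <- grid_sample(vols, c(4, 4, 4))
  expect_length(g, 8)
  starts <- t(vapply(g, `[[`, integer(3), "start"))
  expect_equal(starts, as.matrix(expand.grid(z = c(0L, 4L), y = c(0L, 4L),
                                             x = c(0L, 4L)))[, 3:1],
               ignore_attr = TRUE)

  # 10^3 volume, 4^3 window: per-axis starts {0,4,6} -> 27 windows
  g2 <- grid_sample(make_vols(c(10, 10, 10)), c(4, 4, 4))
  expect_length(g2, 27)
  expect_equal(sort(unique(vapply(g2, function(w) w$start[1], integer(1)))),
               c(0L, 4L, 6L))

  # window == volume: one window at the origin
  g3 <- grid_sample(vols, c(8, 8, 8))
  expect_length(g3, 1)
  expect_equal(g3[[1]]$start, c(0L, 0L, 0L))
  expect_true(g3[[1]]$placement_valid)

  # undersized volume: padded, flagged invalid
  g4 <- grid_sample(make_vols(c(5, 5, 5)), c(8, 8, 8))
  expect_false(g4[[1]]$placement_valid)
  expect_equal(dim(g4[[1]]$arrays$image)[1:3], c(8L, 8L, 8L))

  expect_error(grid_sample(vols, c(4, 4, 4), border = 2), "2\\*border")
})

test_that("grid central regions cover every voxel", {
  set.seed(13)
  for (i in 1:10) {
    shape <- sample(6:14, 3, TRUE)
    win <- pmin(sample(3:8, 3, TRUE), shape)
    border <- pmin(sample(0:2, 3, TRUE), (win - 1L) %/% 2L)
    cover <- array(0L, shape)
    for (w in grid_sample(list(image = array(0, c(shape, 1))), win, border)) {
      lo <- pmax(w$start + border - w$pad_before, 0L)
      hi <- pmin(w$start + win - border - w$pad_before, shape)
      if (any(hi <= lo)) next
      ix <- lapply(1:3, function(k) (lo[k] + 1):hi[k])
      cover[ix[[1]], ix[[2]], ix[[3]]] <- cover[ix[[1]], ix[[2]], ix[[3]]] + 1L
    }
    expect_true(all(cover >= 1L))
  }
})

test_that("resize sampler rescales with shape-identity and label closure", {
  vols <- make_vols(c(8, 8, 8))
  rw <- resize_sample(vols, c(8, 8, 8))
  expect_equal(rw$arrays$image, vols$image)

  cvol <- list(image = array(5, c(8, 8, 8, 1)))
  expect_lt(max(abs(resize_sample(cvol, c(5, 7, 3))$arrays$image - 5)), 1e-12)

  lab <- list(label = array(sample(0:1, 64, TRUE), c(4, 4, 4, 1)))
  expect_true(all(resize_sample(lab, c(2, 2, 2))$arrays$label %in% 0:1))
})

test_that("noise sampler is standard normal and seed-deterministic", {
  z <- sample_noise(100, 10000, rng_stream(5))
  expect_equal(dim(z), c(10000L, 100L))
  expect_lt(max(abs(colMeans(z))), 0.05)
  expect_lt(max(abs(apply(z, 2, var) - 1)), 0.05)
  expect_identical(sample_noise(3, 2, rng_stream(6)), sample_noise(3, 2, rng_stream(6)))
  expect_true(is.finite(sample_noise(1, 1, rng_stream(7))[1, 1]))
})
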