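# driver tests use a deliberately tiny setup: 16^3 single-organ phantoms,
# growth-4 network, 8^3 windows

make_driver_fixture <- function(n_train = 2, seed = 40) {
  base <- tempfile("drv"); dir.create(base)
  data_dir <- file.path(base, "data")
  write_phantom_dataset(phantom_spec(seed = seed, shape = c(16, 16, 16),
                                     n_organs = 1), n_train, data_dir)
  list(base = base, data = data_dir)
}

driver_config <- function(fx, ..., model_dir = file.path(fx$base, "model")) {
  opts <- list(...)
  lines <- c("[system]", "action = train", paste0("model_dir = ", model_dir),
             "seed = 7",
             "[network]", "name = reference_segnet", "n_classes = 2",
             "growth = 4",
             "[training]", "lr = 0.01", "iterations = 10", "save_every = 5",
             "spatial_window_size = 8 8 8", "normalisation = none",
             "augmentation = on",
             "[inference]", "spatial_window_size = 8 8 8", "border = 1 1 1",
             "sampler = grid", "output_kind = label",
             "[image]", paste0("path = ", fx$data), "pattern = _img",
             "[label]", paste0("path = ", fx$data), "pattern = _seg")
  f <- tempfile(fileext = ".ini")
  writeLines(lines, f)
  parse_config(f, opts)
}

test_that("training loop logs every step, checkpoints, and reproduces per seed", {
  fx <- make_driver_fixture()
  cfg <- driver_config(fx)
  res <- run_training(cfg)
  expect_equal(nrow(res$log), 10)
  expect_equal(res$log$step, 1:10)
  ckpts <- list.dirs(file.path(cfg$system$model_dir, "checkpoints"),
                     recursive = FALSE)
  expect_gte(length(ckpts), 1)
  # the checkpoint embeds the full resolved config
  ck <- restore_checkpoint(res$checkpoint_dir)
  expect_equal(ck$config, cfg)

  res2 <- run_training(driver_config(fx, "system.model_dir" = file.path(fx$base, "m2")))
  expect_identical(res$log$loss, res2$log$loss)
})

test_that("resuming from a checkpoint matches the uninterrupted run bitwise", {
  fx <- make_driver_fixture()
  full <- run_training(driver_config(fx, "training.iterations" = "6",
                                     "training.save_every" = "3",
                                     "system.model_dir" = file.path(fx$base, "full")))
  resumed <- run_training(
    driver_config(fx, "training.iterations" = "6", "training.save_every" = "3",
                  "system.model_dir" = file.path(fx$base, "resume")),
    resume_from = file.path(fx$base, "full", "checkpoints", "step_000003"))
  pf <- restore_checkpoint(full$checkpoint_dir)$parameter_map
  pr <- restore_checkpoint(resumed$checkpoint_dir)$parameter_map
  expect_identical(pf, pr)
  expect_identical(full$log$loss[4:6], resumed$log$loss)
})

test_that("identity-network grid inference reproduces inputs end to end", {
  fx <- make_driver_fixture()
  cfg <- driver_config(fx, "network.name" = "identity",
                       "inference.output_kind" = "continuous",
                       "system.action" = "inference")
  out <- run_inference(cfg)
  expect_length(out, 2)
  for (sid in names(out)) {
    got <- load_volume(out[[sid]])
    want <- load_volume(file.path(fx$data, paste0(sid, "_img.nii.gz")))
    expect_lt(max(abs(got$data - want$data)), 1e-6)
  }
  # determinism: running twice gives identical files
  before <- lapply(out, function(p) readBin(p, "raw", file.size(p)))
  out2 <- run_inference(cfg)
  after <- lapply(out2, function(p) readBin(p, "raw", file.size(p)))
  expect_identical(before, after)

  # resize sampler at native shape is also the identity
  cfg2 <- driver_config(fx, "network.name" = "identity",
                        "inference.output_kind" = "continuous",
                        "inference.sampler" = "resize",
                        "inference.spatial_window_size" = "16 16 16",
                        "system.action" = "inference")
  out3 <- run_inference(cfg2)
  got <- load_volume(out3[[1]])
  want <- load_volume(file.path(fx$data, "sub001_img.nii.gz"))
  expect_lt(max(abs(got$data - want$data)), 1e-6)

  expect_error(run_inference(driver_config(fx, "system.action" = "inference")),
               "no checkpoints")
})

test_that("evaluation action reports Dice 1 for copied segmentations", {
  fx <- make_driver_fixture()
  cfg <- driver_config(fx, "system.action" = "evaluation",
                       "evaluation.metrics" = "dice")
  out_dir <- file.path(cfg$system$model_dir, "output")
  dir.create(out_dir, recursive = TRUE)
  for (s in c("sub001", "sub002")) {
    file.copy(file.path(fx$data, paste0(s, "_seg.nii.gz")),
              file.path(out_dir, paste0(s, "_niftynet_out.nii.gz")))
  }
  rep <- run_evaluation(cfg)
  expect_true(all(rep$value[rep$metric == "dice"] == 1))
  expect_true(file.exists(file.path(cfg$system$model_dir, "evaluation.csv")))
})

test_that("linear interpolation hits its endpoint and midpoint identities", {
  cm <- generate_conditioning_map(c(8, 8, 4))
  gen <- demo_generator(16)
  res <- linear_interpolation_inference(gen, cm, n_steps = 3,
                                        rng = rng_stream(9), latent_dim = 16)
  z <- sample_noise(16, 2, rng_stream(9))
  expect_equal(res$z[1, ], z[1, ])
  expect_equal(res$z[3, ], z[2, ])
  expect_lt(max(abs(res$z[2, ] - (z[1, ] + z[2, ]) / 2)), 1e-9)
  expect_equal(res$images[[1]], gen(z[1, ], cm))

  # degenerate z1 == z2: identical images
  same_gen <- function(zv, cond) gen(zv * 0, cond)
  res2 <- linear_interpolation_inference(same_gen, cm, n_steps = 4,
                                         rng = rng_stream(10), latent_dim = 16)
  for (k in 2:4) expect_identical(res2$images[[1]], res2$images[[k]])

  expect_error(linear_interpolation_inference(gen, cm, n_steps = 1,
                                              rng = rng_stream(1)), "n_steps")
})
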