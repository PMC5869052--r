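# The application driver: wires Reader -> Sampler -> Network -> output
# handler for an action, runs it, checkpoints it and logs it.  Single
# process, single device; all randomness flows from the configured master
# seed through named component streams.

# resolve a network factory: a built-in name, a plain function name, or a
# "pkg::fun" plugin path given in the configuration
resolve_network_factory <- function(name) {
  if (name %in% c("reference_segnet", "segnet")) return(build_reference_segnet)
  if (name == "identity") return(build_identity_network)
  if (grepl("::", name, fixed = TRUE)) {
    parts <- strsplit(name, "::", fixed = TRUE)[[1]]
    return(getExportedValue(parts[1], parts[2]))
  }
  f <- mget(name, envir = globalenv(), ifnotfound = list(NULL))[[1]]
  if (is.function(f)) return(f)
  vp_stop("cannot resolve network factory '%s'", name)
}

# build the dataset index described by the configuration's data sections
build_dataset_index <- function(config) {
  specs <- lapply(config$data, function(d)
    list(interpolation = d$interpolation))
  csvs <- vapply(config$data, function(d) d$csv, character(1))
  if (any(nzchar(csvs))) {
    csv <- unique(csvs[nzchar(csvs)])
    vp_assert(length(csv) == 1, "all data sections must share one manifest csv")
    idx <- load_manifest(csv, specs)
    keep <- names(config$data)
    vp_assert(all(keep %in% names(idx$section_specs)),
              "manifest lacks column(s): %s",
              paste(setdiff(keep, names(idx$section_specs)), collapse = ", "))
    idx$subjects <- lapply(idx$subjects, function(s) s[keep])
    idx$section_specs <- idx$section_specs[keep]
    return(idx)
  }
  paths <- vapply(config$data, function(d) d$path, character(1))
  vp_assert(length(unique(paths)) == 1,
            "all pattern-discovered data sections must share one path")
  discover_dataset(paths[1],
                   lapply(config$data, function(d) d$pattern),
                   specs)
}

# load all subjects into memory, with the configured normalization applied
# to sections named "image"
load_training_data <- function(index, config) {
  lapply(setNames(names(index$subjects), names(index$subjects)), function(sid) {
    vols <- load_subject(index, sid)
    if (config$training$normalisation == "meanvar" && "image" %in% names(vols)) {
      vols$image <- meanvar_normalize(vols$image)
    }
    vols
  })
}

log_line <- function(config, txt) {
  log_dir <- file.path(config$system$model_dir, "logs")
  dir.create(log_dir, recursive = TRUE, showWarnings = FALSE)
  cat(txt, "\n", sep = "", file = file.path(log_dir, "run.log"), append = TRUE)
}

#' Run configured training
#'
#' The training loop: sample a window from a random subject, optionally
#' augment it with a random affine transform, run the network forward,
#' compute the configured loss (soft Dice on softmaxed scores, or RMSE),
#' take one Adam step.  A checkpoint embedding the full resolved
#' configuration is written every `save_every` iterations and at the end;
#' with a fixed seed the whole loss trajectory is reproducible, and resuming
#' from a checkpoint reproduces an uninterrupted run exactly (RNG stream and
#' optimizer state are stored in the checkpoint).
#'
#' @param config a config file path or [parse_config()] result.
#' @param resume_from optional checkpoint directory to resume from.
#' @return list with `log` (tibble of step/loss/timestamp), `checkpoint_dir`
#'   (last checkpoint), `store` and `network`, invisibly.
#' @export
run_training <- function(config, resume_from = NULL) {
  config <- parse_config(config)
  tr <- config$training
  seed <- config$system$seed
  index <- build_dataset_index(config)
  data <- load_training_data(index, config)
  subjects <- names(data)
  target_sec <- if (tr$loss == "dice") tr$label_section else tr$target_section
  vp_assert(target_sec %in% names(data[[1]]),
            "training target section '%s' not in data sections (%s)",
            target_sec, paste(names(data[[1]]), collapse = ", "))
  in_channels <- dim(data[[1]]$image$data)[5]
  n_out <- if (tr$loss == "dice") config$network$n_classes else 1L
  factory <- resolve_network_factory(config$network$name)
  network <- factory(in_channels, n_out, config$network)

  sampler_rng <- derive_rng(seed, "sampler")
  aug_rng <- derive_rng(seed, "augmentation")
  store <- vx_param_store(init_rng = derive_rng(seed, "init"))
  opt <- vx_adam(store, lr = tr$lr)
  start_iter <- 0L
  if (!is.null(resume_from)) {
    ck <- restore_checkpoint(resume_from)
    apply_checkpoint(store, ck)
    start_iter <- ck$step
    rs <- ck$run_state
    if (!is.null(rs)) {
      sampler_rng <- restore_rng(rs$rng$sampler)
      aug_rng <- restore_rng(rs$rng$augmentation)
      store$rng <- restore_rng(rs$rng$init)
      opt$t <- rs$adam$t
      for (s in names(rs$adam$m)) opt$m[[s]] <- rs$adam$m[[s]]
      for (s in names(rs$adam$v)) opt$v[[s]] <- rs$adam$v[[s]]
    }
  }
  aug_params <- augmentation_params(flip_axes = tr$flip_axes,
                                    rotation_range_deg = tr$rotation_range,
                                    scaling_range_pct = tr$scaling_range)
  ckpt_root <- file.path(config$system$model_dir, "checkpoints")
  save_state <- function(step) {
    dir <- file.path(ckpt_root, sprintf("step_%06d", step))
    save_checkpoint(store, step, config, dir, run_state = list(
      rng = list(sampler = rng_state(sampler_rng),
                 augmentation = rng_state(aug_rng),
                 init = rng_state(store$rng)),
      adam = list(t = opt$t, m = as.list(opt$m), v = as.list(opt$v))))
    dir
  }
  logs <- vector("list", tr$iterations - start_iter)
  last_ckpt <- NULL
  for (it in seq.int(start_iter + 1L, length.out = tr$iterations - start_iter)) {
    sid <- subjects[[with_rng(sampler_rng, sample.int(length(subjects), 1))]]
    wins <- uniform_sample(data[[sid]], tr$spatial_window_size,
                           tr$samples_per_volume, sampler_rng, subject_id = sid)
    tape <- vx_tape()
    losses <- lapply(wins, function(win) {
      arrays <- win$arrays
      if (tr$augmentation) {
        tf <- sample_affine(aug_params, aug_rng)
        arrays <- apply_transform(arrays, tf, sections = as.list(win$sections))
      }
      x <- vx_const(tape, arrays$image)
      out <- network$forward(store, tape, x)
      if (tr$loss == "dice") {
        op_softmax_dice(tape, out, arrays[[target_sec]][, , , 1],
                        config$network$n_classes)
      } else {
        op_rmse(tape, out, arrays[[target_sec]])
      }
    })
    loss_node <- op_mean_list(tape, losses)
    if (!is.finite(loss_node$value)) {
      vp_stop("non-finite loss (%s) at step %d", format(loss_node$value), it)
    }
    vx_backward(tape, loss_node)
    vx_adam_step(opt, tape)
    logs[[it - start_iter]] <- tibble::tibble(
      step = it, loss = loss_node$value, timestamp = Sys.time())
    log_line(config, sprintf("step %d loss %.6f", it, loss_node$value))
    if (it %% tr$save_every == 0L || it == tr$iterations) {
      last_ckpt <- save_state(it)
    }
  }
  invisible(list(log = dplyr::bind_rows(logs), checkpoint_dir = last_ckpt,
                 store = store, network = network))
}

latest_checkpoint <- function(model_dir) {
  root <- file.path(model_dir, "checkpoints")
  dirs <- sort(list.dirs(root, recursive = FALSE))
  vp_assert(length(dirs) > 0, "no checkpoints under %s", root)
  dirs[length(dirs)]
}

#' Run configured inference
#'
#' For every subject: systematic sampling (grid windows with a border, or
#' whole-volume resize), network forward pass, aggregation back to a
#' whole-volume output, and NIfTI writing as
#' `<subject_id>_niftynet_out.nii.gz` (plus mean class probabilities as
#' `<subject_id>_niftynet_prob.nii.gz` when `save_probabilities` is on).
#' Label outputs accumulate softmaxed per-class scores and take the argmax
#' at finalization; the whole pass is deterministic given the checkpoint.
#'
#' @param config config file path or object; `NULL` uses the checkpoint's
#'   embedded configuration.
#' @param checkpoint checkpoint directory (default: latest under the
#'   configured `model_dir`; the identity network needs none).
#' @return named character vector of output paths, invisibly.
#' @export
run_inference <- function(config = NULL, checkpoint = NULL) {
  ck <- NULL
  if (!is.null(checkpoint)) ck <- restore_checkpoint(checkpoint)
  if (is.null(config)) {
    vp_assert(!is.null(ck) && !is.null(ck$config),
              "no config given and checkpoint has no embedded config")
    config <- ck$config
  }
  config <- parse_config(config)
  inf <- config$inference
  factory <- resolve_network_factory(config$network$name)
  needs_params <- !identical(config$network$name, "identity")
  if (is.null(ck) && needs_params) {
    ck <- restore_checkpoint(latest_checkpoint(config$system$model_dir))
  }
  index <- build_dataset_index(config)
  out_dir <- if (nzchar(inf$output_dir)) inf$output_dir
             else file.path(config$system$model_dir, "output")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  store <- vx_param_store(init_rng = derive_rng(config$system$seed, "init"))
  network <- NULL
  for (sid in names(index$subjects)) {
    vols <- load_subject(index, sid)
    img <- vols$image
    vp_assert(!is.null(img), "inference needs an [image] data section")
    if (config$training$normalisation == "meanvar") img <- meanvar_normalize(img)
    if (is.null(network)) {
      in_channels <- dim(img$data)[5]
      n_out <- if (inf$output_kind == "label") config$network$n_classes else 1L
      network <- factory(in_channels, n_out, config$network)
      if (needs_params) {
        # materialize parameter shapes, then load the checkpoint into them
        dry <- array(0, c(inf$spatial_window_size, in_channels))
        invisible(network_forward(network, store, dry))
        apply_checkpoint(store, ck)
      }
    }
    channels <- network$out_channels %||% config$network$n_classes
    forward_window <- function(arr) {
      out <- network_forward(network, store, arr)
      if (inf$output_kind == "label" && !is.null(network$n_classes) &&
          identical(dim(out)[4], as.integer(channels)) && needs_params) {
        out <- softmax_channels(out)
      }
      out
    }
    if (inf$sampler == "grid") {
      wins <- grid_sample(list(image = img), inf$spatial_window_size,
                          inf$border, subject_id = sid)
      state <- init_grid_aggregation(vol_shape(img), channels, inf$border)
      for (w in wins) accumulate_window(state, w, forward_window(w$arrays$image))
      result <- finalize_aggregation(
        state, if (inf$output_kind == "label" && channels > 1) "label" else "continuous",
        reference = img)
    } else {
      w <- resize_sample(list(image = img), inf$spatial_window_size,
                         subject_id = sid)
      out <- forward_window(w$arrays$image)
      result <- resize_aggregate(out, vol_shape(img),
                                 if (inf$output_kind == "label" && channels > 1)
                                   "label" else "continuous",
                                 reference = img)
    }
    path <- file.path(out_dir, paste0(sid, "_niftynet_out.nii.gz"))
    write_volume(result, path, reference = img)
    outputs[[sid]] <- path
    if (inf$save_probabilities && inf$output_kind == "label") {
      # rerun aggregation output as continuous probabilities
      state2 <- init_grid_aggregation(vol_shape(img), channels, inf$border)
      if (inf$sampler == "grid") {
        for (w in wins) accumulate_window(state2, w, forward_window(w$arrays$image))
        prob <- finalize_aggregation(state2, "continuous", reference = img)
        write_volume(prob, file.path(out_dir, paste0(sid, "_niftynet_prob.nii.gz")),
                     reference = img)
      }
    }
    log_line(config, sprintf("inference %s -> %s", sid, path))
  }
  invisible(outputs)
}

#' Run configured evaluation
#'
#' Delegates to [evaluate_subjects()]: compares the inferred segmentations
#' in the inference output directory with the reference `label` section, and
#' writes `evaluation.csv` into the model directory.
#'
#' @param config config file path or object.
#' @return the metric report tibble, invisibly.
#' @export
run_evaluation <- function(config) {
  config <- parse_config(config)
  index <- build_dataset_index(config)
  seg_dir <- if (nzchar(config$inference$output_dir)) config$inference$output_dir
             else file.path(config$system$model_dir, "output")
  ev <- config$evaluation
  cfg <- list(csv_path = file.path(config$system$model_dir, "evaluation.csv"),
              spacing_units = ev$spacing_units)
  if (nzchar(ev$metrics)) cfg$metrics <- strsplit(ev$metrics, "[,[:space:]]+")[[1]]
  if (length(ev$labels) > 0) cfg$labels <- ev$labels
  report <- evaluate_subjects(index, seg_dir, cfg)
  log_line(config, sprintf("evaluation: %d rows -> %s", nrow(report), cfg$csv_path))
  invisible(report)
}

#' Linear-interpolation inference through a generative model
#'
#' Draws two latent vectors, interpolates `n_steps` model parameters evenly
#' between them, and generates one image per parameter with the SAME
#' conditioning image — the standard probe of a conditional generative
#' model's latent space.
#'
#' @param generator a function `f(z, conditioning)` returning an image
#'   array.
#' @param conditioning conditioning image (e.g. from
#'   [generate_conditioning_map()]) passed to every call.
#' @param n_steps number of interpolation points (>= 2; endpoints are the
#'   two draws themselves).
#' @param rng an [rng_stream()] for the latent draws.
#' @param latent_dim dimension of the latent vectors (default 100).
#' @return list with `z` (n_steps x latent_dim matrix of interpolated
#'   parameters) and `images` (list of generated arrays).
#' @export
linear_interpolation_inference <- function(generator, conditioning = NULL,
                                           n_steps = 8, rng = rng_stream(1),
                                           latent_dim = 100) {
  vp_assert(n_steps >= 2, "n_steps must be >= 2")
  z <- sample_noise(latent_dim, 2, rng)
  alphas <- (seq_len(n_steps) - 1) / (n_steps - 1)
  zi <- t(vapply(alphas, function(a) z[1, ] + a * (z[2, ] - z[1, ]),
                 numeric(latent_dim)))
  images <- lapply(seq_len(n_steps), function(i) generator(zi[i, ], conditioning))
  list(z = zi, images = images)
}

#' Demonstration coordinate-conditioned generator
#'
#' A deterministic toy generator for exercising
#' [linear_interpolation_inference()]: the image is a latent-weighted
#' combination of the conditioning coordinate channels plus a smooth
#' latent-dependent modulation.
#'
#' @param latent_dim latent dimension (>= 4).
#' @return a function `f(z, conditioning)` returning a 3D array.
#' @export
demo_generator <- function(latent_dim = 100) {
  vp_assert(latent_dim >= 4, "latent_dim must be >= 4")
  function(z, conditioning) {
    vp_assert(inherits(conditioning, "image_volume"),
              "conditioning must be an image_volume (coordinate map)")
    cm <- vol_array4(conditioning)
    sh <- dim(cm)[1:3]
    out <- z[4] + z[1] * cm[, , , 1] + z[2] * cm[, , , 2] + z[3] * cm[, , , 3]
    out + sin(2 * pi * (cm[, , , 1] + z[1])) * 0.1
  }
}
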