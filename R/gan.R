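# Adversarial training: the optimizer alternates between the discriminator
# and the generator, each step updating only its own sub-network's
# parameters.

#' One alternating GAN optimization step
#'
#' Step 1 updates ONLY the discriminator's parameters against real-vs-
#' generated binary cross-entropy on its logits; step 2 updates ONLY the
#' generator's parameters with the non-saturating objective (maximize the
#' discriminator's error on generated samples).  The partition is enforced by
#' scope-filtered optimizers, so the untouched sub-network's parameters are
#' bitwise unchanged after the other's step.
#'
#' @param generator,discriminator lists with `forward(store, tape, input,
#'   conditioning)` and `scope` (the sub-network's parameter scope prefix).
#' @param real_batch array/matrix of real samples.
#' @param noise_batch latent input passed to the generator (e.g. from
#'   [sample_noise()]).
#' @param conditioning optional conditioning input given to both networks.
#' @param optimizers list with `discriminator` and `generator` [vx_adam()]
#'   optimizers (scope-filtered to their sub-networks).
#' @param store the shared [vx_param_store()].
#' @return list with `discriminator_loss` and `generator_loss`.
#' @export
gan_alternating_step <- function(generator, discriminator, real_batch,
                                 noise_batch, conditioning = NULL,
                                 optimizers, store) {
  # step 1: discriminator on real vs generated
  tape <- vx_tape()
  fake <- generator$forward(store, tape, vx_const(tape, noise_batch), conditioning)
  d_real <- discriminator$forward(store, tape, vx_const(tape, real_batch), conditioning)
  d_fake <- discriminator$forward(store, tape, fake, conditioning)
  loss_d <- op_add(tape,
                   op_sigmoid_bce(tape, d_real, 1),
                   op_sigmoid_bce(tape, d_fake, 0))
  vx_backward(tape, loss_d)
  vx_adam_step(optimizers$discriminator, tape)
  # step 2: generator against the updated discriminator
  tape2 <- vx_tape()
  fake2 <- generator$forward(store, tape2, vx_const(tape2, noise_batch), conditioning)
  d_fake2 <- discriminator$forward(store, tape2, fake2, conditioning)
  loss_g <- op_sigmoid_bce(tape2, d_fake2, 1)
  vx_backward(tape2, loss_g)
  vx_adam_step(optimizers$generator, tape2)
  list(discriminator_loss = loss_d$value, generator_loss = loss_g$value)
}

#' Scalar toy GAN: shift generator vs logistic discriminator
#'
#' A 1-D exercise of the alternating contract: the generator shifts standard
#' normal noise by a learned scalar, the discriminator is a logistic
#' regression.  Adversarial training should move the generated mean toward
#' the real mean.
#'
#' @param real_mean mean of the real 1-D Gaussian data.
#' @param n_steps alternating steps to run.
#' @param batch batch size per step.
#' @param rng an [rng_stream()] driving data, noise and initialization.
#' @param lr learning rate for both Adam optimizers.
#' @return list with the trained `shift`, `initial_gap`, `final_gap`
#'   (absolute difference between real and generated means, measured on
#'   fresh batches) and the per-step loss tibble `log`.
#' @export
run_toy_gan <- function(real_mean = 3, n_steps = 500, batch = 64,
                        rng = rng_stream(1), lr = 0.05) {
  store <- vx_param_store(init_rng = derive_rng(rng$seed, "init"))
  generator <- list(
    scope = "gen",
    forward = function(store, tape, z, conditioning = NULL) {
      b <- vx_param(store, tape, "gen/shift", 1L, "zeros")
      op_add_scalar(tape, z, b)
    })
  discriminator <- list(
    scope = "disc",
    forward = function(store, tape, x, conditioning = NULL) {
      w <- vx_param(store, tape, "disc/w", 1L, "ones")
      c <- vx_param(store, tape, "disc/c", 1L, "zeros")
      op_scale_shift(tape, x, w, c)
    })
  opts <- list(discriminator = vx_adam(store, lr = lr, scopes = "disc"),
               generator = vx_adam(store, lr = lr, scopes = "gen"))
  data_rng <- derive_rng(rng$seed, "data")
  noise_rng <- derive_rng(rng$seed, "noise")
  eval_gap <- function() {
    real <- with_rng(data_rng, rnorm(1000, real_mean))
    z <- with_rng(noise_rng, rnorm(1000))
    abs(mean(real) - mean(z + store$params[["gen/shift"]][1]))
  }
  # materialize parameters once so the initial gap sees the initial shift
  tape0 <- vx_tape()
  invisible(generator$forward(store, tape0, vx_const(tape0, 0)))
  invisible(discriminator$forward(store, tape0, vx_const(tape0, 0)))
  initial_gap <- eval_gap()
  log <- vector("list", n_steps)
  for (i in seq_len(n_steps)) {
    real <- with_rng(data_rng, rnorm(batch, real_mean))
    z <- with_rng(noise_rng, rnorm(batch))
    losses <- gan_alternating_step(generator, discriminator, real, z,
                                   optimizers = opts, store = store)
    log[[i]] <- tibble::tibble(step = i,
                               discriminator_loss = losses$discriminator_loss,
                               generator_loss = losses$generator_loss)
  }
  list(shift = store$params[["gen/shift"]][1],
       initial_gap = initial_gap,
       final_gap = eval_gap(),
       log = dplyr::bind_rows(log))
}
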