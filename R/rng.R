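#' Named reproducible RNG streams
#'
#' All randomness in a voxpipe run flows from one master seed.  Each pipeline
#' component (sampler, augmentation, noise, parameter initialization, ...)
#' draws from its own named stream, so that adding draws to one component does
#' not shift the sequences seen by the others.  A stream keeps its own
#' `.Random.seed` state; [with_rng()] swaps it in around an expression and
#' captures the advanced state afterwards, leaving the caller's global RNG
#' untouched.
#'
#' @param seed integer seed for this stream, or a master seed for
#'   [derive_rng()].
#' @param name stream name; the child seed is a deterministic hash of
#'   `(master seed, name)`.
#' @return an object of class `rng_stream`.
#' @examples
#' s <- rng_stream(7)
#' a <- with_rng(s, rnorm(3))
#' b <- with_rng(rng_stream(7), rnorm(3))
#' stopifnot(identical(a, b))
#' @export
rng_stream <- function(seed) {
  vp_assert(is_scalar_number(seed), "seed must be a single number")
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(seed) %% .Machine$integer.max
  e$state <- NULL
  class(e) <- "rng_stream"
  e
}

# FNV-1a string hash folded into a positive 31-bit integer
hash_name <- function(name) {
  h <- 2166136261
  for (b in utf8ToInt(name)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% (2^31 - 1))
}

#' @rdname rng_stream
#' @export
derive_rng <- function(seed, name) {
  vp_assert(is.character(name) && length(name) == 1L, "name must be a string")
  rng_stream((as.integer(seed) %% 2^30 + hash_name(name)) %% (2^31 - 1))
}

#' @rdname rng_stream
#' @param stream an `rng_stream`.
#' @param expr expression evaluated with the stream's RNG state active.
#' @export
with_rng <- function(stream, expr) {
  vp_assert(inherits(stream, "rng_stream"), "with_rng needs an rng_stream")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  if (is.null(stream$state)) {
    set.seed(stream$seed)
  } else {
    assign(".Random.seed", stream$state, envir = globalenv())
  }
  res <- expr
  stream$state <- get(".Random.seed", globalenv())
  res
}

# snapshot/restore for checkpointing
rng_state <- function(stream) list(seed = stream$seed, state = stream$state)

restore_rng <- function(snapshot) {
  s <- rng_stream(snapshot$seed)
  s$state <- snapshot$state
  s
}
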