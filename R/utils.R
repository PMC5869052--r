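`%||%` <- function(a, b) if (is.null(a)) b else a

vp_stop <- function(...) stop(sprintf(...), call. = FALSE)

vp_assert <- function(cond, ...) if (!isTRUE(cond)) vp_stop(...)

# integer triple coercion with validation
as_int3 <- function(x, what = "value") {
  if (length(x) == 1L) x <- rep(x, 3L)
  vp_assert(length(x) == 3L && all(is.finite(x)), "%s must be 3 finite numbers", what)
  as.integer(round(x))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
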