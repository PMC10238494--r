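# Internal helpers shared across modules.

# Run expr with a locally seeded RNG, restoring global .Random.seed on exit.
# All stochastic operations route through this so no function touches global
# RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index, staying below
# 2^31 so it is always a valid R integer.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 7919) %% 2147483629)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
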