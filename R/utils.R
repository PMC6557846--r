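# Internal helpers shared across modules.

# Horner evaluation of a polynomial with coefficients highest-degree-first,
# the convention used throughout (cubic drift = c(a, b, c, d)).
eval_poly <- function(coeffs, x) {
  v <- rep(0, length(x))
  for (ci in coeffs) v <- v * x + ci
  v
}

# Deterministic substream seed derived from a master seed and index path.
# Linear congruential mixing keeps results < 2^31 and independent of the
# order in which units are generated, so per-trial (or per-run) regeneration
# does not depend on loop order.
substream_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) {
    s <- (s * 48271 + (as.double(i) + 1) * 9349 + 1) %% 2147483647
  }
  as.integer(s)
}

# Run code under a local, seeded RNG without disturbing the caller's RNG.
with_substream <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

# Floor applied to the noise amplitude so the SDE stays well defined when a
# fitted h(z) dips to or below zero (model units).
NOISE_EPS <- 1e-6
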