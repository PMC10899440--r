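# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All exported stochastic functions route
# their randomness through this so that a seed argument fully determines
# the result without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic child seed derivation; keeps results below 2^31 - 1 so the
# value is a valid R integer seed.
derive_seed <- function(master, i) {
  x <- (as.double(master) %% 2147483647) * 69069 + 101 * as.double(i)
  as.integer(x %% 2147483646) + 1L
}

# One draw per element from a normal truncated to [lo, hi] via inverse CDF,
# consuming exactly length(mu) uniforms from the current RNG stream.
rtruncnorm01 <- function(n, mu, sd, lo = 0, hi = 1) {
  plo <- pnorm(lo, mu, sd)
  phi_ <- pnorm(hi, mu, sd)
  qnorm(plo + runif(n) * (phi_ - plo), mu, sd)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == as.integer(x) && x >= 0
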