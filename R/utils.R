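# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a child seed from a master seed and counter indices
#'
#' One master seed drives every random component; per-patient, per-slice and
#' per-run seeds are derived with a multiplicative-congruential step so that
#' distinct counter paths give uncorrelated, reproducible streams. Results
#' stay below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param ... integer counters (e.g. class index, patient index, slice index).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (k in c(...)) {
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

# evaluate `code` under `seed` without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# population standard deviation (divisor N, matching the texture formulas)
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
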