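# Self-contained random number streams. Each stream owns a private copy of
# R's RNG state, so package randomness never disturbs (or depends on) the
# caller's global RNG, and a single run seed can fan out into independent
# named sub-streams (data, augmentation, init, batch order).

#' Create a seeded random number stream
#'
#' @param seed Integer seed.
#' @return An object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  seed <- as.integer(seed %% 2147483647)
  s <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  s$state <- get(".Random.seed", envir = globalenv())
  s$seed <- seed
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(s) <- "rng_stream"
  s
}

with_rng <- function(s, fn) {
  stopifnot(inherits(s, "rng_stream"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", s$state, envir = globalenv())
  on.exit({
    s$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  fn()
}

rng_runif <- function(s, n, min = 0, max = 1) with_rng(s, function() stats::runif(n, min, max))
rng_rnorm <- function(s, n, mean = 0, sd = 1) with_rng(s, function() stats::rnorm(n, mean, sd))
rng_sample <- function(s, x, size = length(x), replace = FALSE) {
  with_rng(s, function() sample(x, size, replace))
}
rng_int <- function(s, n, lo, hi) {
  # uniform integers in [lo, hi]
  lo + floor(rng_runif(s, n) * (hi - lo + 1))
}

#' Derive a deterministic sub-seed from a run seed and a stream name
#'
#' @param seed Integer run seed.
#' @param key Character stream name.
#' @return An integer below 2^31 usable as a seed.
#' @export
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}
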