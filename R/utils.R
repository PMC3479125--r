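#' Round half away from zero
#'
#' Decimal rounding with the half-up convention (0.5 always rounds away from
#' zero), matching the rounding used for reported percentages and fold
#' changes. Base [round()] uses banker's rounding and is not suitable for
#' reproducing printed integers.
#'
#' @param x numeric vector.
#' @param digits number of decimal places; may be negative (e.g. `-1` rounds
#'   to the nearest ten).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.5)        # 1
#' round_half_up(8.379)      # 8
#' round_half_up(177.62, -1) # 180
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Convert minutes to seconds
#'
#' @param min_ time in minutes.
#' @return time in seconds.
#' @export
#' @examples
#' min_to_s(30.61)  # 1836.6
min_to_s <- function(min_) min_ * 60

#' Convert seconds to minutes
#' @param s time in seconds.
#' @return time in minutes.
#' @export
s_to_min <- function(s) s / 60

#' Derive a child RNG seed from a master seed
#'
#' All stochastic functions in the package draw from streams derived from a
#' single master seed so that, e.g., the same gating path can be re-rendered
#' with a different noise realization. The derivation is a Lehmer-style step
#' kept below 2^31 so the result is always a valid integer seed.
#'
#' @param seed master seed (integer).
#' @param salt integer distinguishing the stream.
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, salt) {
  m <- 2147483647
  as.integer(((as.numeric(seed) %% m) * 48271 + as.numeric(salt) * 9973 + 1) %% m)
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# near-equality helper for internal floating point checks
.near <- function(a, b, tol = 1e-9) abs(a - b) <= tol * pmax(1, abs(a), abs(b))
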