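#' Round half away from zero
#'
#' Rounding used for all reported detection rates: halves round away from
#' zero (0.985 -> 0.99), unlike [base::round()]'s round-half-even. A guard of
#' 1e-9 absorbs the binary representation error of decimal halves arising
#' from count ratios; it cannot flip a non-half case for any ratio with a
#' denominator below 1e5, because the distance of such a ratio to the
#' half-way point is at least 1/(2 * denominator).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_away(153 / 155, 2)  # 0.99
#' round_half_away(0.125, 2)      # 0.13
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Format a rate for reporting
#'
#' @param x numeric vector of rates.
#' @param digits decimal places (2 by default, as in the benchmark tables;
#'   3 for finer reporting such as 0.036).
#' @return character vector.
#' @export
format_rate <- function(x, digits = 2) {
  formatC(round_half_away(x, digits), format = "f", digits = digits)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Quantize a real-valued stack to integer digital numbers
#'
#' Values are clipped to \[0, 1\] and scaled to the target bit depth with
#' round-half-up.
#'
#' @param x numeric array (or `image_stack`) with values in \[0, 1\].
#' @param depth bit depth, 8 or 16.
#' @return integer-valued array of the same shape.
#' @export
quantize_values <- function(x, depth = 8L) {
  stopifnot(depth %in% c(8L, 16L))
  floor(clip01(x) * (2^depth - 1) + 0.5)
}

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that package internals never
#' perturb a caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
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

# Seed-splitting scheme: one master seed deterministically yields one
# sub-seed per named stage, so stages can be re-run independently.
stage_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
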