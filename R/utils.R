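#' Round half away from zero
#'
#' Rounding rule used for all integerisation and reported percentages:
#' ties go away from zero (`round_half_up(0.5) == 1`), unlike base
#' [round()], which rounds half to even. ActiGraph-style exports and the
#' tabulated percentages in this field use half-up rounding.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.345), c(0, 0, 2))
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one master seed; each stage /
#' participant / day draws from its own sub-stream so stages can be re-run
#' independently. The sub-stream seed is a deterministic 31-bit hash of the
#' master seed and a sequence of labels.
#'
#' @param master integer master seed.
#' @param ... labels (character or integer scalars) identifying the stream.
#' @return an integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @examples
#' substream_seed(1, "states", "P001", 2)
#' @export
substream_seed <- function(master, ...) {
  stopifnot(length(master) == 1, is.finite(master))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(master) %% m
  for (lab in list(...)) {
    codes <- if (is.character(lab)) utf8ToInt(lab) else as.integer(lab)
    for (cc in codes) {
      h <- (h * 48271 + as.numeric(cc) + 1) %% m
    }
  }
  as.integer(h)
}

# internal: stop() with call. = FALSE everywhere
abort <- function(...) stop(..., call. = FALSE)

# internal: check a probability vector
is_prob_vector <- function(p, tol = 1e-12) {
  is.numeric(p) && all(p >= 0) && abs(sum(p) - 1) <= tol
}
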