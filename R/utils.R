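#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; published tables in this field
#' round half up. \code{round_half_up(17.6)} is 18, \code{round_half_up(2.45, 1)}
#' is 2.5.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive per-stage seeds from one run seed
#'
#' Each pipeline stage gets its own reproducible seed so stages can be
#' re-run independently. Stage seeds are `seed * 1000 + offset` folded into
#' the 32-bit integer range.
#'
#' @param seed integer master seed.
#' @param stage integer stage counter (>= 1).
#' @return a single integer seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + 97 * stage) %% .Machine$integer.max)
}

# internal: stop() with a consistent message prefix
abort_input <- function(...) stop(..., call. = FALSE)
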