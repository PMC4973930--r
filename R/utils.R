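## Internal helpers: classed conditions, seeded RNG, reporting-precision rounding.

#' @keywords internal
cbjf_abort <- function(code, message, ...) {
  stop(structure(
    list(message = sprintf(message, ...), call = sys.call(-1)),
    class = c(code, "cbjf_error", "error", "condition")
  ))
}

#' @keywords internal
cbjf_warn <- function(code, message, ...) {
  warning(structure(
    list(message = sprintf(message, ...), call = sys.call(-1)),
    class = c(code, "cbjf_warning", "warning", "condition")
  ))
}

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
#' @keywords internal
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

#' Round half away from zero
#'
#' Decimal rounding used when comparing fitted tables with printed references:
#' values exactly halfway between two decimals round away from zero
#' (0.0625 -> 0.063 at 3 digits), unlike [round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## Numeric formatting for file output: full round-trip precision.
#' @keywords internal
fmt_num <- function(x) sprintf("%.17g", x)
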