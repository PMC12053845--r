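#' Round half away from zero
#'
#' Deterministic commercial rounding used throughout the package for
#' reporting: predicted counts round to whole cases, RSVI ratios display at
#' 3 decimals and percentage errors at 1 decimal. Exact .5 ties move away
#' from zero, unlike [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded, same length.
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5), 0)   # 1  2 -1
#' round_half_away(98 / 90, 3)             # 1.089
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# condition helpers backing the CLI exit-code contract:
# input/validation problems vs configuration problems
stop_input <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "rsvicast_input_error")
}

stop_config <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "rsvicast_config_error")
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_config("`%s` must be a single non-missing number", name)
  }
  invisible(x)
}
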