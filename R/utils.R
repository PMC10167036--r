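## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
hgo_log <- function(..., verbose = getOption("hgonet.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[hgonet] ", ...)
  invisible(NULL)
}

#' @noRd
stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Round half away from zero
#'
#' Presentation rounding used for reported kinetic constants: halves are
#' rounded away from zero (so 0.125 -> 0.13), unlike [round()]'s banker's
#' rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(0.125, 2)  # 0.13, where round() gives 0.12
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  # repair binary-representation error before applying the half-up rule,
  # so that a decimal half (e.g. 0.285 at 2 dp) always rounds away from zero
  sign(x) * floor(round(abs(x) * p, 9) + 0.5) / p
}

## run code with a temporary, restored RNG state
#' @noRd
with_seed <- function(seed, code) withr::with_seed(seed, code)
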