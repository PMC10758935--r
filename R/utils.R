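# Small shared helpers. Kept internal.

DAYS_PER_MONTH <- 30.44

#' Round half away from zero
#'
#' Base `round()` rounds halves to even; clinical tables round 0.5 up.
#' @param x numeric vector
#' @param digits integer, decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Integer percentage as printed in clinical report tables
#'
#' Computed via a one-decimal intermediate (`round(100*num/den, 1)` then
#' half-up to an integer), the convention under which a fraction such as
#' 63/66 (95.45%) prints as 96.
#' @param num,den numerators and denominators
#' @return integer vector of percentages
#' @keywords internal
report_pct <- function(num, den) {
  as.integer(round_half_up(round_half_up(100 * num / den, 1)))
}

# plain half-up percentage (demographic tables)
plain_pct <- function(num, den) {
  as.integer(round_half_up(100 * num / den))
}

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
  invisible(NULL)
}

check_integerish <- function(x, what) {
  abort_if(!is.numeric(x) || any(is.na(x)) || any(x != floor(x)),
           sprintf("%s must be whole numbers without missing values", what))
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
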