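# Small shared helpers.

#' Round to one decimal, half away from zero
#'
#' Cohort diagnostic rates are printed to one decimal with half-up rounding
#' (35/36 -> 97.2, 10/12 -> 83.3), unlike base [round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stopifnot() with a formatted message
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
}

# max over possibly all-NA vector, -Inf when empty/all NA
max_or <- function(x, default = -Inf) {
  x <- x[!is.na(x)]
  if (length(x) == 0) default else max(x)
}
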