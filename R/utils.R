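#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves rounded up (away from
#' zero), the convention used when reporting registry percentages.
#' Base R's `round()` rounds halves to even, which would turn 0.585% into
#' 0.58% instead of the reported 0.6%.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(2.25, 2.35), 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop with a classed condition so callers/tests can distinguish
# configuration errors from validation errors
stop_vetlink <- function(msg, class) {
  abort(msg, class = c(class, "vetlink_error"))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

check_fraction <- function(value, field) {
  if (!is_scalar_number(value) || value < 0 || value > 1) {
    stop_vetlink(
      sprintf("`%s` must be a single number in [0, 1], got %s",
              field, paste(format(value), collapse = ", ")),
      "vetlink_config_error"
    )
  }
  invisible(value)
}

check_count <- function(value, field, min = 1) {
  if (!is_scalar_number(value) || value < min || value != floor(value)) {
    stop_vetlink(
      sprintf("`%s` must be a whole number >= %d, got %s",
              field, min, paste(format(value), collapse = ", ")),
      "vetlink_config_error"
    )
  }
  invisible(as.integer(value))
}
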