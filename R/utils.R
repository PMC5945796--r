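# Internal validation helpers. All user-facing errors are rlang conditions
# with a class so callers (and the CLI) can distinguish config errors from
# data errors.

abort_domain <- function(msg, ...) abort(msg, class = "hipscreen_domain_error", ...)
abort_data <- function(msg, ...) abort(msg, class = "hipscreen_data_error", ...)
abort_config <- function(msg, ...) abort(msg, class = "hipscreen_config_error", ...)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_lower = TRUE, allow_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_domain(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (allow_lower) x >= lower else x > lower
  hi_ok <- if (allow_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort_domain(sprintf(
      "`%s` = %g is outside its valid range %s%g, %g%s.",
      name, x,
      if (allow_lower) "[" else "(", lower, upper,
      if (allow_upper) "]" else ")"
    ))
  }
  invisible(x)
}

check_positive <- function(x, name) check_number(x, name, lower = 0, allow_lower = FALSE)
check_nonneg <- function(x, name) check_number(x, name, lower = 0)

#' Format a fraction as a percentage string
#'
#' Probabilities and rates are carried as fractions internally; this helper
#' applies percent formatting only at the reporting boundary, rounding to a
#' fixed number of significant figures (e.g. `0.000784` prints as
#' `"0.0784%"`).
#'
#' @param x Numeric vector of fractions (1 = 100%).
#' @param sig_figs Significant figures kept in the percentage.
#' @return Character vector like `"0.0784%"`.
#' @export
#' @examples
#' format_percent(c(0.00196, 0.000784, 8.008e-05))
format_percent <- function(x, sig_figs = 4) {
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(NA_character_)
    paste0(format(signif(100 * xi, sig_figs), scientific = FALSE,
                  trim = TRUE, drop0trailing = TRUE), "%")
  }, character(1))
}

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Pounds formatting for reports: nearest pound unless pence = TRUE.
format_gbp <- function(x, pence = FALSE) {
  digits <- if (pence) 2 else 0
  paste0("£", formatC(round_half_up(x, digits), format = "f",
                           digits = digits, big.mark = ","))
}
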