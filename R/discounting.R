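#' Present value of a future stream
#'
#' End-of-year discounting: `PV = sum_t v_t (1 + rate)^-t` for
#' `t = 1, ..., length(values)`. Used for lifetime benefit streams (days or
#' AUD per future year).
#'
#' @param values Numeric vector, one element per future year (year 1 first).
#' @param rate Annual discount rate, `>= 0`.
#' @return The present value (single number).
#' @export
#' @examples
#' discount_stream(c(100), 0.03)   # 97.0874
#' discount_stream(rep(1, 10), 0)  # 10
discount_stream <- function(values, rate) {
  assert_number(rate, "rate", min = 0)
  if (length(values) == 0) return(0)
  if (any(!is.finite(values))) {
    abort("`values` must be finite.", class = "inactcost_validation_error")
  }
  sum(values / (1 + rate)^seq_along(values))
}

# Present value of 1 per year for `years` years (fractional years allowed:
# the trailing fraction of a year accrues pro rata at its year-end weight).
annuity_factor <- function(years, rate) {
  if (length(years) > 1L) {
    return(vapply(years, annuity_factor, numeric(1), rate = rate))
  }
  if (years <= 0) return(0)
  n <- floor(years)
  frac <- years - n
  full <- if (n == 0) 0 else if (rate == 0) n else
    (1 - (1 + rate)^-n) / rate
  full + frac / (1 + rate)^(n + 1)
}
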