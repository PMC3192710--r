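#' Annual health-sector opportunity-cost savings
#'
#' Applies the scenario's impact fraction to the annual health-sector cost of
#' treating incident cases attributable to physical inactivity. This is a
#' deliberately conservative annual (not lifetime) accounting: one year's
#' attributable treatment cost approximates the savings, so savings can never
#' exceed one year's attributable cost.
#'
#' The share of total health-system cost is reported against
#' `total_system_cost`, which defaults to `attributable_cost / 0.013`
#' (attributable cost is 1.3% of total annual health-sector cost in the
#' calibrated inputs); override it when a measured system total is available.
#'
#' @param attributable_cost Attributable annual health-sector cost, AUD
#'   million/yr, `>= 0`.
#' @param spec A [scenario_spec()].
#' @param rr Optional relative risk passed through to [impact_fraction()]
#'   when `spec$method == "pif"` (a single aggregate RR; per-disease
#'   application happens upstream in [avert_burden()]).
#' @param total_system_cost Total annual health-system cost, AUD million/yr;
#'   default derived from the 1.3% attributable share.
#' @return A one-row `health_cost_result` tibble: `savings` (AUD
#'   million/yr), `share_of_attributable`, `share_of_total_system`,
#'   `total_system_cost`.
#' @export
#' @examples
#' health_cost_savings(672, scenario_spec("feasible"))    # AUD96M
#' health_cost_savings(672, scenario_spec("elimination")) # AUD672M
health_cost_savings <- function(attributable_cost, spec, rr = NULL,
                                total_system_cost = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  assert_number(attributable_cost, "attributable_cost", min = 0)
  f <- impact_fraction(spec$baseline_prevalence, spec$delta_pp, spec$method,
                       rr = rr)
  if (is.null(total_system_cost)) {
    total_system_cost <- attributable_cost / 0.013
  }
  savings <- attributable_cost * f
  out <- tibble::tibble(
    savings = savings,
    share_of_attributable = if (attributable_cost > 0) savings / attributable_cost else 0,
    share_of_total_system = if (total_system_cost > 0) savings / total_system_cost else 0,
    total_system_cost = total_system_cost
  )
  class(out) <- c("health_cost_result", class(out))
  out
}
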