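#' Define a prevalence-reduction scenario
#'
#' A scenario is an absolute percentage-point reduction in the prevalence of
#' physical inactivity, together with the impact-fraction method, discounting
#' and production-valuation choices used downstream. Three named targets are
#' packaged: `"feasible"` (10 percentage points off a 70% baseline),
#' `"progressive"` (5 points), and `"elimination"` (the full baseline, i.e.
#' a theoretical-minimum comparison).
#'
#' The default impact-fraction method is `"proportional"` (averted burden
#' scales as `delta_pp / baseline_prevalence`); `"pif"` is a documented
#' alternative that works through relative risks (see [impact_fraction()]).
#'
#' @param target `"feasible"`, `"progressive"`, `"elimination"`, or
#'   `"custom"` (then supply `delta_pp`).
#' @param delta_pp Absolute percentage-point reduction as a fraction (0.10 =
#'   ten points); required for `target = "custom"`, otherwise implied.
#' @param baseline_prevalence Baseline inactivity prevalence, in (0, 1].
#' @param method Impact-fraction method, `"proportional"` or `"pif"`.
#' @param discount_rate Annual discount rate for lifetime benefits
#'   (default 0.03; sensitivity values 0, 0.05, 0.07).
#' @param valuation Paid-production valuation, `"FCA"` (friction cost,
#'   default) or `"HCA"` (human capital).
#' @param friction_months Friction period in months (default 3;
#'   sensitivity 6).
#' @return An object of class `scenario_spec`.
#' @export
#' @examples
#' scenario_spec("feasible")
#' scenario_spec("custom", delta_pp = 0.2, discount_rate = 0.05)
scenario_spec <- function(target = c("feasible", "progressive", "elimination",
                                     "custom"),
                          delta_pp = NULL,
                          baseline_prevalence = 0.70,
                          method = c("proportional", "pif"),
                          discount_rate = 0.03,
                          valuation = c("FCA", "HCA"),
                          friction_months = 3) {
  target <- match.arg(target)
  method <- match.arg(method)
  valuation <- match.arg(valuation)
  assert_number(baseline_prevalence, "baseline_prevalence", min = 1e-12, max = 1)
  assert_number(discount_rate, "discount_rate", min = 0)
  assert_number(friction_months, "friction_months", min = 1e-12)
  delta_pp <- switch(target,
    feasible = 0.10,
    progressive = 0.05,
    elimination = baseline_prevalence,
    custom = {
      if (is.null(delta_pp)) {
        abort("`delta_pp` is required when target = \"custom\".",
              class = "inactcost_config_error")
      }
      delta_pp
    })
  assert_number(delta_pp, "delta_pp", min = 0, max = baseline_prevalence)
  structure(
    list(target = target, delta_pp = delta_pp,
         baseline_prevalence = baseline_prevalence, method = method,
         discount_rate = discount_rate, valuation = valuation,
         friction_months = friction_months),
    class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec> %s: -%.1f pp from %.0f%% prevalence (%s method)\n",
    x$target, 100 * x$delta_pp, 100 * x$baseline_prevalence, x$method))
  cat(sprintf("  discount %.0f%%/yr, valuation %s, friction %g months\n",
              100 * x$discount_rate, x$valuation, x$friction_months))
  invisible(x)
}

#' Impact fraction of a prevalence reduction
#'
#' Fraction of attributable burden averted by reducing exposure prevalence
#' from `p0` to `p0 - delta_pp`.
#'
#' * `method = "proportional"`: `f = delta_pp / p0`, the relative change in
#'   prevalence. Applied to *attributable* burden this is the simplification
#'   under which averted burden scales linearly with the prevalence shift.
#' * `method = "pif"`: the potential-impact-fraction route through the
#'   population attributable fraction `PAF(p) = p(RR-1) / (1 + p(RR-1))`:
#'   `f = [PAF(p0) - PAF(p1)] / PAF(p0)` with `p1 = p0 - delta_pp`. Requires
#'   a relative risk `rr >= 1` and is vectorised over `rr`.
#'
#' For `rr -> 1` the PIF route converges to the proportional fraction; for
#' `rr > 1` it is strictly smaller.
#'
#' @param p0 Baseline prevalence, in (0, 1].
#' @param delta_pp Absolute percentage-point reduction (fraction), in
#'   `[0, p0]`.
#' @param method `"proportional"` or `"pif"`.
#' @param rr Relative risk (scalar or vector), required for `"pif"`.
#' @return Dimensionless fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' impact_fraction(0.70, 0.10)                      # 1/7
#' impact_fraction(0.70, 0.10, "pif", rr = 2)
impact_fraction <- function(p0, delta_pp,
                            method = c("proportional", "pif"), rr = NULL) {
  method <- match.arg(method)
  assert_number(p0, "p0", min = 1e-12, max = 1)
  if (!is.numeric(delta_pp) || length(delta_pp) != 1L || !is.finite(delta_pp) ||
      delta_pp < 0 || delta_pp > p0 + 1e-12) {
    abort("`delta_pp` must be a single number in [0, p0].",
          class = "inactcost_domain_error")
  }
  if (method == "proportional") {
    return(min(1, delta_pp / p0))
  }
  if (is.null(rr)) {
    abort("method = \"pif\" requires a relative risk `rr`.",
          class = "inactcost_config_error")
  }
  if (any(!is.finite(rr)) || any(rr < 1)) {
    abort("`rr` must be finite and >= 1.", class = "inactcost_domain_error")
  }
  paf <- function(p, rr) p * (rr - 1) / (1 + p * (rr - 1))
  p1 <- p0 - delta_pp
  f <- ifelse(rr == 1, delta_pp / p0,
              (paf(p0, rr) - paf(p1, rr)) / paf(p0, rr))
  pmin(1, pmax(0, f))
}

#' Averted attributable burden under a scenario
#'
#' Multiplies every attributable quantity of the burden table (incident
#' cases, deaths, DALYs, health-sector cost, production loss) by the
#' scenario's impact fraction — per-disease relative risks are used when
#' `spec$method == "pif"` — without mutating the input.
#'
#' @param burden The `burden` tibble of an [generate_inputs()] bundle (or any
#'   tibble with the same columns).
#' @param spec A [scenario_spec()].
#' @return A `burden_reduction` tibble: `disease`, `sex`, `age_band`,
#'   `averted_cases`, `averted_deaths`, `averted_dalys`,
#'   `averted_health_cost`, `averted_production_loss`, plus attributes
#'   `totals` (named national totals) and `spec`. [glance()] returns the
#'   totals as a one-row tibble.
#' @export
#' @examples
#' b <- generate_inputs(2008)
#' red <- avert_burden(b$burden, scenario_spec("feasible"))
#' glance(red)
avert_burden <- function(burden, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  need <- c("disease", "sex", "age_band", "cases", "deaths", "dalys",
            "health_cost", "production_loss")
  if (!is.data.frame(burden) || nrow(burden) == 0 ||
      !all(need %in% names(burden))) {
    abort("`burden` must be a non-empty attributable burden table.",
          class = "inactcost_validation_error")
  }
  f <- if (spec$method == "proportional") {
    impact_fraction(spec$baseline_prevalence, spec$delta_pp, "proportional")
  } else {
    impact_fraction(spec$baseline_prevalence, spec$delta_pp, "pif",
                    rr = burden$relative_risk)
  }
  out <- tibble::tibble(
    disease = burden$disease, sex = burden$sex, age_band = burden$age_band,
    averted_cases = f * burden$cases,
    averted_deaths = f * burden$deaths,
    averted_dalys = f * burden$dalys,
    averted_health_cost = f * burden$health_cost,
    averted_production_loss = f * burden$production_loss
  )
  totals <- c(
    averted_cases = sum(out$averted_cases),
    averted_deaths = sum(out$averted_deaths),
    averted_dalys = sum(out$averted_dalys),
    averted_health_cost = sum(out$averted_health_cost),
    averted_production_loss = sum(out$averted_production_loss)
  )
  structure(out, totals = totals, spec = spec,
            class = c("burden_reduction", class(out)))
}

#' @export
glance.burden_reduction <- function(x, ...) {
  tibble::as_tibble(as.list(attr(x, "totals")))
}

#' @export
tidy.burden_reduction <- function(x, ...) {
  out <- x
  attributes(out)[c("totals", "spec")] <- NULL
  class(out) <- setdiff(class(out), "burden_reduction")
  tibble::as_tibble(out)
}
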