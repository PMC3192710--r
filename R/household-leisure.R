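#' Lifetime unpaid-production and leisure day gains from averted burden
#'
#' On a day of ill-health-reduced activity, neither the household duties nor
#' the leisure normally undertaken happen; a gained day therefore counts
#' toward *both* the home-production and the leisure pool. Per averted case
#' or death, the annual gain is the annualized difference in mean days of
#' reduced activity between the exposed and non-exposed stratum, accrued
#' over the stratum's remaining life expectancy and discounted at the
#' scenario rate. Days are split by workforce status (using the non-exposed
#' participation rate) so they can be valued against status-specific
#' time-use profiles.
#'
#' @param averted A [avert_burden()] result.
#' @param labor Bundle `labor` tibble.
#' @param economics Bundle `economics` tibble (remaining life expectancy).
#' @param spec A [scenario_spec()].
#' @return A tibble by `sex` x `age_band` x `workforce` (`"in"`/`"out"`)
#'   with column `days`; attributes `home_days` and `leisure_days` hold the
#'   (equal) pool totals.
#' @export
unpaid_day_gains <- function(averted, labor, economics, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  s <- collapse_strata(averted, averted$averted_cases + averted$averted_deaths)
  le <- stratum_index(s$key, labor, labor$activity == "exposed")
  ln <- stratum_index(s$key, labor, labor$activity == "non_exposed")
  ie <- stratum_index(s$key, economics)
  annual <- annualize_fortnight_days(labor$days_reduced_activity[le]) -
    annualize_fortnight_days(labor$days_reduced_activity[ln])
  days <- s$w * annual *
    annuity_factor(economics$remaining_life_expectancy[ie],
                   spec$discount_rate)
  ilf <- labor$in_labor_force[ln]
  n <- length(days)
  split <- tibble::tibble(
    sex = rep(s$sex, 2), age_band = rep(s$age_band, 2),
    workforce = rep(c("in", "out"), each = n),
    days = c(days * ilf, days * (1 - ilf))
  )
  structure(split, home_days = sum(split$days), leisure_days = sum(split$days))
}

blended_replacement_rate <- function(params) {
  w <- params$childcare_weight
  (1 - w) * params$replacement_rate_domestic +
    w * params$replacement_rate_childcare
}

#' Value home-production days at replacement cost
#'
#' A gained day restores `household_hours_per_day` hours of unpaid household
#' production, valued at the blended commercial replacement rate (a
#' configurable mix of domestic-services and child-care hourly wages):
#' `value = days x hours/day x AUD/hour`.
#'
#' Pass either the stratified day-gain tibble from [unpaid_day_gains()]
#' (hours then come from the matching `timeuse` stratum) or a plain number
#' of days with explicit `hours` and `rate`.
#'
#' @param days [unpaid_day_gains()] tibble, or a number of days.
#' @param timeuse Bundle `timeuse` tibble (stratified path).
#' @param params Bundle `params` list (replacement rates and blend weight).
#' @param hours,rate Hours/day and AUD/hour for the scalar path (defaults:
#'   mean profile hours; blended rate from `params`).
#' @return Value in AUD.
#' @export
#' @examples
#' value_home_production(1, hours = 4, rate = 25)  # 100
value_home_production <- function(days, timeuse = NULL, params = NULL,
                                  hours = NULL, rate = NULL) {
  if (is.null(rate)) {
    if (is.null(params)) {
      abort("Provide `rate` or `params` for the replacement rate.",
            class = "inactcost_config_error")
    }
    rate <- blended_replacement_rate(params)
  }
  if (rate < 0) {
    abort("Replacement rate must be >= 0.",
          class = "inactcost_validation_error")
  }
  if (is.numeric(days)) {
    if (any(days < 0)) {
      abort("`days` must be >= 0.", class = "inactcost_validation_error")
    }
    if (is.null(hours)) hours <- mean(timeuse$household_hours)
    return(sum(days) * hours * rate)
  }
  i <- match(paste(days$sex, days$age_band, days$workforce),
             paste(timeuse$sex, timeuse$age_band, timeuse$workforce))
  if (anyNA(i)) {
    abort("`timeuse` is missing strata present in `days`.",
          class = "inactcost_data_error")
  }
  sum(days$days * timeuse$household_hours[i] * rate)
}

#' Value leisure days by the opportunity-cost method
#'
#' Leisure time is priced at one third of average weekly earnings, converted
#' to an hourly rate through the standard working week:
#' `price = (weekly_earnings / 3) / standard_weekly_hours`, and
#' `value = days x leisure_hours/day x price`.
#'
#' @param days [unpaid_day_gains()] tibble, or a number of days.
#' @param timeuse Bundle `timeuse` tibble (stratified path).
#' @param economics Bundle `economics` tibble (stratum weekly earnings).
#' @param params Bundle `params` list (`standard_weekly_hours`).
#' @param hours,weekly_earnings Leisure hours/day and AUD/week for the
#'   scalar path.
#' @param standard_weekly_hours Hours in a standard working week (default
#'   from `params`, 38).
#' @return Value in AUD.
#' @export
#' @examples
#' value_leisure(1, hours = 5, weekly_earnings = 1140,
#'               standard_weekly_hours = 38)  # 50
value_leisure <- function(days, timeuse = NULL, economics = NULL,
                          params = NULL, hours = NULL, weekly_earnings = NULL,
                          standard_weekly_hours = NULL) {
  if (is.null(standard_weekly_hours)) {
    standard_weekly_hours <- params$standard_weekly_hours
  }
  if (is.null(standard_weekly_hours) || standard_weekly_hours <= 0) {
    abort("`standard_weekly_hours` must be > 0.",
          class = "inactcost_config_error")
  }
  if (is.numeric(days)) {
    if (any(days < 0)) {
      abort("`days` must be >= 0.", class = "inactcost_validation_error")
    }
    if (is.null(hours)) hours <- mean(timeuse$leisure_hours)
    if (is.null(weekly_earnings)) weekly_earnings <- mean(economics$weekly_earnings)
    return(sum(days) * hours * (weekly_earnings / 3) / standard_weekly_hours)
  }
  i <- match(paste(days$sex, days$age_band, days$workforce),
             paste(timeuse$sex, timeuse$age_band, timeuse$workforce))
  if (anyNA(i)) {
    abort("`timeuse` is missing strata present in `days`.",
          class = "inactcost_data_error")
  }
  ie <- stratum_index(paste(days$sex, days$age_band, sep = "\r"), economics)
  sum(days$days * timeuse$leisure_hours[i] *
        (economics$weekly_earnings[ie] / 3) / standard_weekly_hours)
}
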