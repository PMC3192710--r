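#' Annualize a two-week recall day rate
#'
#' Survey day rates (days off work, days of reduced activity) are recorded
#' per two-week recall period; a year holds 26 fortnights.
#'
#' @param rate Days per fortnight, in `[0, 14]` (vectorised).
#' @return Days per year (`rate * 26`).
#' @export
#' @examples
#' annualize_fortnight_days(0.32)  # 8.32
annualize_fortnight_days <- function(rate) {
  if (!is.numeric(rate) || any(!is.finite(rate)) ||
      any(rate < 0) || any(rate > 14)) {
    abort("`rate` must be days per fortnight in [0, 14].",
          class = "inactcost_validation_error")
  }
  rate * 26
}

#' Lifetime discounted absenteeism-day gains from averted cases
#'
#' Each averted incident case adopts the non-exposed absenteeism profile
#' instead of the exposed one. The annual gain per case is the labour-force
#' participation of the non-exposed stratum times the annualized difference
#' in mean days off work (exposed minus non-exposed), accrued over the
#' stratum's remaining working years and discounted at the scenario rate.
#'
#' @param averted A [avert_burden()] result (or tibble with `sex`,
#'   `age_band`, `averted_cases`).
#' @param labor Bundle `labor` tibble.
#' @param economics Bundle `economics` tibble (supplies
#'   `remaining_working_years`).
#' @param spec A [scenario_spec()] (supplies the discount rate).
#' @return A tibble by `sex` x `age_band` with column `days` (lifetime,
#'   discounted), with attribute `total_days`.
#' @export
absenteeism_gain <- function(averted, labor, economics, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  s <- collapse_strata(averted, averted$averted_cases)
  le <- stratum_index(s$key, labor, labor$activity == "exposed")
  ln <- stratum_index(s$key, labor, labor$activity == "non_exposed")
  ie <- stratum_index(s$key, economics)
  annual <- labor$in_labor_force[ln] *
    (annualize_fortnight_days(labor$days_off_work[le]) -
       annualize_fortnight_days(labor$days_off_work[ln]))
  days <- s$w * annual *
    annuity_factor(economics$remaining_working_years[ie],
                   spec$discount_rate)
  out <- tibble::tibble(sex = s$sex, age_band = s$age_band, days = days)
  structure(out, total_days = sum(days))
}

# Aggregate a stratified table to sex x age_band, preserving input order of
# first appearance; `w` is the weight column to sum.
collapse_strata <- function(tbl, w) {
  key <- paste(tbl$sex, tbl$age_band, sep = "\r")
  first <- !duplicated(key)
  keys <- key[first]
  sums <- rowsum(w, key)[keys, ]
  list(key = keys, sex = tbl$sex[first], age_band = tbl$age_band[first],
       w = as.numeric(sums))
}

# Row indices of `tbl` (optionally filtered) matching sex x age_band keys;
# errors if any stratum is missing.
stratum_index <- function(keys, tbl, subset = NULL) {
  rows <- if (is.null(subset)) seq_len(nrow(tbl)) else which(subset)
  idx <- rows[match(keys, paste(tbl$sex[rows], tbl$age_band[rows],
                                sep = "\r"))]
  if (anyNA(idx)) {
    abort("labor/economics tables are missing strata present in the input.",
          class = "inactcost_data_error")
  }
  idx
}

#' Derive workforce-exit events from averted burden
#'
#' The working-lifetime cohort model needs counts of people who would have left
#' the workforce (death, permanent disability, early retirement) but no
#' longer do. Averted working-age deaths map to death events directly;
#' permanent-disability exits and early retirements are fixture-supplied
#' fractions of averted working-age incident cases (the sources do not
#' publish severity splits).
#'
#' @param averted A [avert_burden()] result.
#' @param params Bundle `params` list (uses `disability_exit_fraction`,
#'   `early_retirement_fraction`, `retirement_age`).
#' @return A tibble of `CohortExitEvent`s: `sex`, `age_band`, `kind`,
#'   `count`.
#' @export
derive_exit_events <- function(averted, params) {
  wk <- averted[age_band_midpoint(averted$age_band) < params$retirement_age, ]
  deaths <- collapse_strata(wk, wk$averted_deaths)
  cases <- collapse_strata(wk, wk$averted_cases)
  n <- length(deaths$key)
  tibble::tibble(
    sex = rep(deaths$sex, 3),
    age_band = rep(deaths$age_band, 3),
    kind = rep(c("death", "permanent_disability_exit", "early_retirement"),
               each = n),
    count = c(deaths$w, cases$w * params$disability_exit_fraction,
              cases$w * params$early_retirement_fraction)
  )
}

value_absenteeism_days <- function(days_tbl, economics) {
  if (is.numeric(days_tbl)) return(0)  # scalar day totals carry no wage detail
  i <- stratum_index(paste(days_tbl$sex, days_tbl$age_band, sep = "\r"),
                     economics)
  sum(days_tbl$days * economics$weekly_earnings[i] / 5)
}

production_result <- function(valuation, production_aud, recruitment_aud,
                              absenteeism_days, early_retirements, tax_rate) {
  out <- tibble::tibble(
    valuation = valuation,
    production_value = production_aud / 1e6,
    taxation_value = taxation_effect(production_aud, tax_rate) / 1e6,
    recruitment_training_value = recruitment_aud / 1e6,
    absenteeism_days = absenteeism_days,
    early_retirements_averted = early_retirements
  )
  class(out) <- c("production_result", class(out))
  out
}

#' Friction-cost valuation of workforce production gains
#'
#' Under the friction-cost approach a worker lost to death or permanent
#' disability is replaced after a friction period; society's production loss
#' is the wages of that period plus the cost of recruiting and training the
#' replacement. Averted exits therefore save, per event,
#' `weekly_earnings x in_labor_force x friction_months x 52/12` weeks of
#' production, plus `recruitment_training_cost x in_labor_force`. Lifetime
#' discounted absenteeism-day gains (valued at a fifth of weekly earnings
#' per working day) are added to the production value.
#'
#' @param events Exit-event tibble from [derive_exit_events()].
#' @param labor Bundle `labor` tibble (non-exposed participation is used).
#' @param economics Bundle `economics` tibble (weekly earnings).
#' @param params Bundle `params` list (recruitment cost, tax rate).
#' @param spec A [scenario_spec()] (`friction_months`).
#' @param absenteeism Optional [absenteeism_gain()] result to fold in.
#' @return A one-row `production_result` tibble (AUD million):
#'   `production_value`, `taxation_value`, `recruitment_training_value`,
#'   `absenteeism_days`, `early_retirements_averted`.
#' @export
fca_value <- function(events, labor, economics, params, spec,
                      absenteeism = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  ev <- join_event_economics(events, labor, economics)
  if (any(ev$weekly_earnings < 0)) {
    abort("negative weekly earnings.", class = "inactcost_validation_error")
  }
  friction_weeks <- spec$friction_months * 52 / 12
  replaced <- ev$kind %in% c("death", "permanent_disability_exit",
                             "early_retirement")
  production <- sum(ev$count * ev$in_labor_force * ev$weekly_earnings *
                      friction_weeks)
  recruitment <- sum(ev$count[replaced] * ev$in_labor_force[replaced]) *
    params$recruitment_training_cost
  abs_days <- 0
  if (!is.null(absenteeism)) {
    production <- production + value_absenteeism_days(absenteeism, economics)
    abs_days <- attr(absenteeism, "total_days") %||% sum(absenteeism$days)
  }
  production_result("FCA", production, recruitment, abs_days,
                    sum(ev$count[ev$kind == "early_retirement"]),
                    params$effective_tax_rate)
}

#' Human-capital valuation of workforce production gains
#'
#' Counts all future income up to the retirement age as saved when a
#' workforce exit is averted: per event,
#' `sum_{t=1..T} annual_earnings x in_labor_force x (1+r)^-t` with `T` the
#' stratum's remaining working years (end-of-year discounting). Events at or
#' beyond the retirement age contribute zero. Recruitment/training costs do
#' not arise under this valuation.
#'
#' @inheritParams fca_value
#' @return A one-row `production_result` tibble (AUD million).
#' @export
hca_value <- function(events, labor, economics, params, spec,
                      absenteeism = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  ev <- join_event_economics(events, labor, economics)
  production <- sum(ev$count * ev$in_labor_force * ev$weekly_earnings * 52 *
                      annuity_factor(ev$remaining_working_years,
                                     spec$discount_rate))
  abs_days <- 0
  if (!is.null(absenteeism)) {
    production <- production + value_absenteeism_days(absenteeism, economics)
    abs_days <- attr(absenteeism, "total_days") %||% sum(absenteeism$days)
  }
  production_result("HCA", production, 0, abs_days,
                    sum(ev$count[ev$kind == "early_retirement"]),
                    params$effective_tax_rate)
}

join_event_economics <- function(events, labor, economics) {
  if (nrow(events) == 0) {
    return(tibble::tibble(sex = character(), age_band = character(),
                          kind = character(), count = numeric(),
                          in_labor_force = numeric(),
                          weekly_earnings = numeric(),
                          remaining_working_years = numeric()))
  }
  keys <- paste(events$sex, events$age_band, sep = "\r")
  il <- stratum_index(keys, labor, labor$activity == "non_exposed")
  ie <- stratum_index(keys, economics)
  tibble::tibble(
    sex = events$sex, age_band = events$age_band, kind = events$kind,
    count = events$count,
    in_labor_force = labor$in_labor_force[il],
    weekly_earnings = economics$weekly_earnings[ie],
    remaining_working_years = economics$remaining_working_years[ie]
  )
}

#' Taxation effect of a production change
#'
#' Flat effective tax rate on the production value: the share of averted
#' production losses that would have been foregone tax revenue.
#'
#' @param production_value Production value, `>= 0` (any currency unit).
#' @param tax_rate Effective tax rate in `[0, 1]`.
#' @return `production_value * tax_rate`.
#' @export
#' @examples
#' taxation_effect(100, 0.17)  # 17
taxation_effect <- function(production_value, tax_rate) {
  if (!is.numeric(production_value) || any(production_value < 0)) {
    abort("`production_value` must be >= 0.",
          class = "inactcost_validation_error")
  }
  if (!is.numeric(tax_rate) || length(tax_rate) != 1L ||
      !is.finite(tax_rate) || tax_rate < 0 || tax_rate > 1) {
    abort("`tax_rate` must be a single number in [0, 1].",
          class = "inactcost_config_error")
  }
  production_value * tax_rate
}
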