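# Shared fixtures, built once per test run.

default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_inputs(2008, "table1_default")
    cache
  }
})

feasible <- function(...) scenario_spec("feasible", ...)

# One-stratum tables for hand-arithmetic oracles.
one_stratum_labor <- function(sex = "male", age_band = "40-44",
                              ilf_exp = 0.75, ilf_non = 0.75,
                              doff_exp = 0.32, doff_non = 0.26,
                              dred_exp = 1.93, dred_non = 0.88) {
  tibble::tibble(
    sex = sex, age_band = age_band,
    activity = c("exposed", "non_exposed"),
    in_labor_force = c(ilf_exp, ilf_non), in_labor_force_se = 0,
    days_off_work = c(doff_exp, doff_non), days_off_work_se = 0,
    days_reduced_activity = c(dred_exp, dred_non),
    days_reduced_activity_se = 0
  )
}

one_stratum_economics <- function(sex = "male", age_band = "40-44",
                                  weekly_earnings = 1000,
                                  working_years = 10, life_years = 40) {
  tibble::tibble(
    sex = sex, age_band = age_band,
    weekly_earnings = weekly_earnings, weekly_earnings_se = 0,
    remaining_life_expectancy = life_years,
    remaining_working_years = working_years
  )
}

one_stratum_averted <- function(sex = "male", age_band = "40-44",
                                cases = 1, deaths = 0) {
  tibble::tibble(
    disease = "d", sex = sex, age_band = age_band,
    averted_cases = cases, averted_deaths = deaths, averted_dalys = 0,
    averted_health_cost = 0, averted_production_loss = 0
  )
}

one_event <- function(sex = "male", age_band = "60-64", kind = "death",
                      count = 1) {
  tibble::tibble(sex = sex, age_band = age_band, kind = kind, count = count)
}

default_params <- function(...) {
  p <- calibration_profiles()$table1_default$params
  modifyList(p, list(...))
}

# Scale every survey SE in a bundle by a common factor.
scale_bundle_ses <- function(bundle, factor) {
  bundle$population$count_se <- bundle$population$count_se * factor
  se_cols <- grep("_se$", names(bundle$labor), value = TRUE)
  bundle$labor[se_cols] <- lapply(bundle$labor[se_cols], `*`, factor)
  bundle$economics$weekly_earnings_se <-
    bundle$economics$weekly_earnings_se * factor
  bundle
}
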