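#' Calibration profiles for the synthetic-data generator
#'
#' A calibration profile pins the synthetic input bundle to published
#' population-level anchors: stratum totals with 95% confidence intervals,
#' labour-force participation and days-out-of-role rates by sex, age grouping
#' and activity status, the disease list with relative risks and burden
#' shares, time-use hours, and the 2008 AUD economic parameters. The packaged
#' `"table1_default"` profile reproduces the published national survey
#' anchors (e.g. 70% adult inactivity prevalence; 0.32 vs 0.26 mean fortnight
#' days off work for inactive vs active working males).
#'
#' Standard errors are recovered from printed 95% CIs as
#' `se = (upper - lower) / 3.92`.
#'
#' @return A named list of profiles; each profile is a named list of
#'   calibration tables and scalars consumed by [generate_inputs()].
#' @seealso [generate_inputs()]
#' @export
#' @examples
#' names(calibration_profiles())
calibration_profiles <- function() {
  list(table1_default = profile_table1_default())
}

profile_table1_default <- function() {
  # Population totals (persons) with 95% CIs, by sex x age grouping x status.
  pop <- tibble::tribble(
    ~sex,     ~age_group, ~activity,     ~count,   ~lo,      ~hi,
    "male",   "15-64",    "exposed",     4332994,  4229842,  4436146,
    "male",   "15-64",    "non_exposed", 2322617,  2220059,  2425175,
    "male",   "65+",      "exposed",      775817,   746962,   804671,
    "male",   "65+",      "non_exposed",  342985,   313395,   372575,
    "female", "15-64",    "exposed",     4798508,  4704081,  4892935,
    "female", "15-64",    "non_exposed", 1864120,  1769404,  1958836,
    "female", "65+",      "exposed",     1059103,  1028507,  1089698,
    "female", "65+",      "non_exposed",  260571,   230005,   291136
  )

  # Labour-force participation (proportion) by sex x age grouping x status.
  participation <- tibble::tribble(
    ~sex,     ~age_group, ~activity,     ~p,    ~lo,   ~hi,
    "male",   "15-64",    "exposed",     0.75,  0.73,  0.76,
    "male",   "15-64",    "non_exposed", 0.75,  0.73,  0.77,
    "female", "15-64",    "exposed",     0.57,  0.56,  0.58,
    "female", "15-64",    "non_exposed", 0.65,  0.63,  0.67,
    "male",   "65+",      "exposed",     0.152, 0.146, 0.158,
    "male",   "65+",      "non_exposed", 0.129, 0.118, 0.140,
    "female", "65+",      "exposed",     0.181, 0.175, 0.187,
    "female", "65+",      "non_exposed", 0.123, 0.108, 0.138
  )

  # Mean days off work per two-week recall (persons in the labour force).
  days_off <- tibble::tribble(
    ~sex,     ~activity,     ~d,    ~lo,   ~hi,
    "male",   "exposed",     0.32,  0.26,  0.38,
    "male",   "non_exposed", 0.26,  0.18,  0.34,
    "female", "exposed",     0.31,  0.26,  0.35,
    "female", "non_exposed", 0.23,  0.16,  0.29
  )

  # Mean days of reduced activity per fortnight, by sex x age grouping x status.
  days_reduced <- tibble::tribble(
    ~sex,     ~age_group, ~activity,     ~d,    ~lo,   ~hi,
    "male",   "15-64",    "exposed",     1.93,  1.60,  2.26,
    "male",   "15-64",    "non_exposed", 0.88,  0.54,  1.21,
    "female", "15-64",    "exposed",     1.45,  1.26,  1.65,
    "female", "15-64",    "non_exposed", 0.84,  0.62,  1.05,
    "male",   "65+",      "exposed",     1.56,  1.25,  1.87,
    "male",   "65+",      "non_exposed", 0.43,  0.22,  0.65,
    "female", "65+",      "exposed",     1.75,  1.53,  1.96,
    "female", "65+",      "non_exposed", 0.73,  0.50,  0.96
  )

  # Inactivity-related diseases: share of attributable burden, relative risk
  # (inactive vs active), male share, and the age shape of the burden.
  # DALY shares: IHD 51%, type 2 diabetes 20%, stroke 14%; the remaining 15%
  # split evenly across colon cancer, depression and fall-related fracture.
  diseases <- tibble::tribble(
    ~disease,                ~share, ~relative_risk, ~male_share, ~age_shape,
    "ischemic_heart_disease", 0.51,  1.45,           0.60,        "chronic",
    "type2_diabetes",         0.20,  1.30,           0.55,        "chronic",
    "stroke",                 0.14,  1.60,           0.50,        "chronic",
    "colon_cancer",           0.05,  1.40,           0.55,        "chronic",
    "depression",             0.05,  1.30,           0.40,        "younger",
    "fall_fracture",          0.05,  1.45,           0.35,        "older"
  )

  # Age shapes: unnormalised weights over the fifteen 5-year bands 15-19..85+.
  age_shapes <- list(
    pop_1564 = c(1.00, 1.02, 1.05, 1.05, 1.08, 1.10, 1.05, 0.98, 0.90, 0.82),
    pop_65p  = c(1.00, 0.85, 0.65, 0.45, 0.35),
    chronic  = c(0.2, 0.3, 0.5, 1, 2, 4, 7, 11, 16, 20, 22, 20, 16, 12, 9),
    younger  = c(6, 9, 11, 12, 12, 11, 10, 9, 8, 7, 5, 4, 3, 2, 1),
    older    = c(0.1, 0.1, 0.2, 0.3, 0.5, 1, 2, 4, 7, 11, 16, 20, 22, 20, 16)
  )

  # Time use (hours/day) by sex x workforce status; constant across age bands.
  timeuse <- tibble::tribble(
    ~sex,     ~workforce, ~household_hours, ~leisure_hours,
    "male",   "in",       1.8,              4.0,
    "male",   "out",      2.8,              6.5,
    "female", "in",       3.3,              3.8,
    "female", "out",      4.8,              6.0
  )

  # Average weekly earnings (2008 AUD) age profile: multiplier on the sex peak.
  wage_profile <- c(0.45, 0.75, 0.95, 1.00, 1.00, 0.98, 0.95, 0.90, 0.82,
                    0.70, 0.40, 0.30, 0.25, 0.25, 0.25)
  wages <- list(
    peak = c(male = 1300, female = 980),
    profile = wage_profile,
    rel_se = 0.02  # survey SE as a fraction of the mean
  )

  # Remaining life expectancy (years) at the band midpoint, 2008-era levels.
  life_expectancy <- list(
    male   = c(62.4, 57.6, 52.8, 48.0, 43.3, 38.6, 34.0, 29.5, 25.1, 20.9,
               16.9, 13.2, 9.9, 7.2, 4.9),
    female = c(66.6, 61.7, 56.8, 52.0, 47.1, 42.3, 37.6, 32.9, 28.3, 23.8,
               19.5, 15.4, 11.8, 8.5, 5.8)
  )

  params <- list(
    baseline_prevalence = 0.70,
    replacement_rate_domestic = 31,    # AUD/hour, 2008 commercial rate
    replacement_rate_childcare = 19,   # AUD/hour
    childcare_weight = 0.25,           # blend weight on the child-care rate
    effective_tax_rate = 0.17,
    recruitment_training_cost = 5200,  # AUD per workforce replacement
    standard_weekly_hours = 38,
    price_index_multiplier = 1.0,      # inputs already in 2008 AUD
    ppp_aud_per_usd = 1.48,
    disability_exit_fraction = 0.04,   # averted cases causing permanent exit
    early_retirement_fraction = 0.003, # averted cases causing early retirement
    retirement_age = 65,
    # Lognormal sd (log scale) of the within-band allocation jitter.
    allocation_jitter_sd = 0.05
  )

  default_targets <- c(
    cases = 45000, deaths = 13000, dalys = 174000,
    health_cost = 672e6, production_loss = 1135e6
  )

  list(
    population = pop,
    participation = participation,
    days_off = days_off,
    days_reduced = days_reduced,
    diseases = diseases,
    age_shapes = age_shapes,
    timeuse = timeuse,
    wages = wages,
    life_expectancy = life_expectancy,
    params = params,
    default_targets = default_targets
  )
}
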