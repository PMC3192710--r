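test_that("fortnight day rates annualize by the 26-fortnight year", {
  expect_equal(annualize_fortnight_days(0), 0)
  expect_equal(annualize_fortnight_days(1.0), 26)
  expect_equal(annualize_fortnight_days(0.32), 8.32)
  expect_error(annualize_fortnight_days(15),
               class = "inactcost_validation_error")
  expect_error(annualize_fortnight_days(-0.1),
               class = "inactcost_validation_error")
})

test_that("absenteeism gains match the hand-arithmetic oracle", {
  # 1 case x participation 0.75 x 0.06 days/fortnight x 26 x 10 years, r = 0
  averted <- one_stratum_averted(cases = 1)
  labor <- one_stratum_labor(ilf_non = 0.75, doff_exp = 0.06, doff_non = 0)
  econ <- one_stratum_economics(working_years = 10)
  spec0 <- scenario_spec("feasible", discount_rate = 0)
  g <- absenteeism_gain(averted, labor, econ, spec0)
  expect_equal(attr(g, "total_days"), 0.06 * 26 * 0.75 * 10)  # 11.7
  # discounting strictly reduces the lifetime total
  g3 <- absenteeism_gain(averted, labor, econ,
                         scenario_spec("feasible", discount_rate = 0.03))
  expect_lt(attr(g3, "total_days"), attr(g, "total_days"))
  # zero averted cases gain nothing
  g0 <- absenteeism_gain(one_stratum_averted(cases = 0), labor, econ, spec0)
  expect_equal(attr(g0, "total_days"), 0)
  # a stratum missing from the labor table is a data error
  expect_error(
    absenteeism_gain(one_stratum_averted(age_band = "50-54"), labor, econ,
                     spec0),
    class = "inactcost_data_error")
})

test_that("friction-cost valuation prices the friction period in weeks", {
  labor <- one_stratum_labor(age_band = "60-64", ilf_non = 1)
  econ <- one_stratum_economics(age_band = "60-64", weekly_earnings = 1000,
                                working_years = 3)
  ev <- one_event(count = 1)
  p <- default_params(recruitment_training_cost = 0)
  r3 <- fca_value(ev, labor, econ, p, scenario_spec("feasible"))
  expect_equal(r3$production_value * 1e6, 1000 * 13)  # 3 months = 13 weeks
  r6 <- fca_value(ev, labor, econ, p,
                  scenario_spec("feasible", friction_months = 6))
  expect_equal(r6$production_value, 2 * r3$production_value)
  empty <- fca_value(one_event(count = 1)[0, ], labor, econ, p, feasible())
  expect_equal(empty$production_value, 0)
  expect_equal(empty$recruitment_training_value, 0)
  expect_equal(empty$early_retirements_averted, 0)
})

test_that("recruitment/training costs count replaced workers only", {
  labor <- one_stratum_labor(age_band = "60-64", ilf_non = 0.8)
  econ <- one_stratum_economics(age_band = "60-64", working_years = 3)
  p <- default_params(recruitment_training_cost = 5000)
  ev <- dplyr::bind_rows(one_event(kind = "death", count = 2),
                         one_event(kind = "permanent_disability_exit",
                                   count = 1))
  r <- fca_value(ev, labor, econ, p, feasible())
  expect_equal(r$recruitment_training_value * 1e6, 3 * 0.8 * 5000)
})

test_that("human-capital valuation matches the closed-form annuity oracle", {
  # one death at 5 working years remaining, annual earnings 50,000, r = 3%
  labor <- one_stratum_labor(age_band = "60-64", ilf_non = 1)
  econ <- one_stratum_economics(age_band = "60-64",
                                weekly_earnings = 50000 / 52,
                                working_years = 5)
  r <- hca_value(one_event(count = 1), labor, econ, default_params(),
                 scenario_spec("feasible", discount_rate = 0.03,
                               valuation = "HCA"))
  oracle <- sum(50000 / 1.03^(1:5))  # end-of-year sum, 228,985.4
  expect_equal(r$production_value * 1e6, oracle, tolerance = 1e-9)
  expect_equal(oracle, 50000 * (1 - 1.03^-5) / 0.03, tolerance = 1e-12)
  # undiscounted: exactly five years of earnings
  r0 <- hca_value(one_event(count = 1), labor, econ, default_params(),
                  scenario_spec("feasible", discount_rate = 0,
                                valuation = "HCA"))
  expect_equal(r0$production_value * 1e6, 250000)
  # at or beyond retirement age the event contributes nothing
  econ65 <- one_stratum_economics(age_band = "65-69", working_years = 0,
                                  life_years = 17)
  labor65 <- one_stratum_labor(age_band = "65-69")
  r65 <- hca_value(one_event(age_band = "65-69"), labor65, econ65,
                   default_params(), feasible())
  expect_equal(r65$production_value, 0)
})

test_that("taxation is a flat configurable rate", {
  expect_equal(taxation_effect(100, 0.17), 17)
  expect_equal(taxation_effect(0, 0.3), 0)
  expect_equal(taxation_effect(100, 0), 0)
  expect_error(taxation_effect(100, 1.2), class = "inactcost_config_error")
  expect_error(taxation_effect(-5, 0.2), class = "inactcost_validation_error")
})

test_that("FCA production value never exceeds HCA on random cohorts", {
  # discount 0 and remaining working earnings >= friction-period earnings
  set.seed(401)
  for (i in 1:25) {
    n <- sample(1:6, 1)
    bands <- sample(c("25-29", "35-39", "45-49", "55-59"), n, replace = TRUE)
    sexes <- sample(c("male", "female"), n, replace = TRUE)
    key <- !duplicated(paste(sexes, bands))
    labor <- purrr::list_rbind(purrr::map2(
      sexes[key], bands[key],
      ~ one_stratum_labor(sex = .x, age_band = .y,
                          ilf_non = stats::runif(1, 0.3, 1))))
    econ <- purrr::list_rbind(purrr::map2(
      sexes[key], bands[key],
      ~ one_stratum_economics(sex = .x, age_band = .y,
                              weekly_earnings = stats::runif(1, 200, 2000),
                              working_years = stats::runif(1, 1, 40))))
    ev <- tibble::tibble(sex = sexes, age_band = bands,
                         kind = sample(c("death", "permanent_disability_exit"),
                                       n, replace = TRUE),
                         count = stats::runif(n, 0, 100))
    sp <- scenario_spec("feasible", discount_rate = 0)
    p <- default_params(recruitment_training_cost = 0)
    expect_lte(fca_value(ev, labor, econ, p, sp)$production_value,
               hca_value(ev, labor, econ, p, sp)$production_value)
  }
})

test_that("HCA value decreases in the discount rate; FCA is rate-invariant", {
  labor <- one_stratum_labor(age_band = "40-44", ilf_non = 0.9)
  econ <- one_stratum_economics(age_band = "40-44", working_years = 22)
  ev <- one_event(age_band = "40-44")
  p <- default_params()
  vals <- vapply(c(0, 0.03, 0.05, 0.07), function(r) {
    hca_value(ev, labor, econ, p,
              scenario_spec("feasible", discount_rate = r))$production_value
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  fca <- vapply(c(0, 0.03, 0.07), function(r) {
    fca_value(ev, labor, econ, p,
              scenario_spec("feasible", discount_rate = r))$production_value
  }, numeric(1))
  expect_equal(fca[1], fca[2])
  expect_equal(fca[1], fca[3])
})

test_that("monetary outputs are degree-1 homogeneous in wages", {
  b <- default_bundle()
  b2 <- b
  b2$economics$weekly_earnings <- 2 * b2$economics$weekly_earnings
  sp <- feasible()
  g1 <- glance(run_scenario(b, sp))
  g2 <- glance(run_scenario(b2, sp))
  expect_equal(g2$workforce_production, 2 * g1$workforce_production)
  expect_equal(g2$taxation, 2 * g1$taxation)
  expect_equal(g2$leisure_production, 2 * g1$leisure_production)
  expect_equal(g2$recruitment_training, g1$recruitment_training)  # not a wage
  expect_equal(g2$absenteeism_days, g1$absenteeism_days)          # days, not AUD
})

test_that("early retirements scale linearly with averted cases", {
  b <- default_bundle()
  e10 <- glance(run_scenario(b, scenario_spec("feasible")))
  e5 <- glance(run_scenario(b, scenario_spec("progressive")))
  expect_equal(e5$early_retirements_averted,
               e10$early_retirements_averted / 2, tolerance = 1e-12)
  # persons, not thousands: a feasible scenario averts tens of retirements
  expect_gt(e10$early_retirements_averted, 1)
  expect_lt(e10$early_retirements_averted, 100)
})
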