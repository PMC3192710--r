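test_that("unpaid day gains match hand arithmetic and fill both pools", {
  # 1 averted case x 1.0 day/fortnight differential x 26 x 10 years, r = 0
  averted <- one_stratum_averted(cases = 1)
  labor <- one_stratum_labor(dred_exp = 1.0, dred_non = 0)
  econ <- one_stratum_economics(life_years = 10)
  g <- unpaid_day_gains(averted, labor, econ,
                        scenario_spec("feasible", discount_rate = 0))
  expect_equal(attr(g, "home_days"), 260)
  expect_equal(attr(g, "leisure_days"), 260)
  expect_equal(attr(g, "home_days"), attr(g, "leisure_days"))
  # zero averted burden gains nothing
  g0 <- unpaid_day_gains(one_stratum_averted(cases = 0), labor, econ,
                         feasible())
  expect_equal(attr(g0, "home_days"), 0)
  expect_equal(attr(g0, "leisure_days"), 0)
})

test_that("the 65+ female day differential annualizes as printed rates imply", {
  # 1.75 - 0.73 days/fortnight x 26 = 26.52 days/yr per averted case
  averted <- one_stratum_averted(sex = "female", age_band = "70-74",
                                 cases = 1)
  labor <- one_stratum_labor(sex = "female", age_band = "70-74",
                             dred_exp = 1.75, dred_non = 0.73)
  econ <- one_stratum_economics(sex = "female", age_band = "70-74",
                                life_years = 1, working_years = 0)
  g <- unpaid_day_gains(averted, labor, econ,
                        scenario_spec("feasible", discount_rate = 0))
  expect_equal(attr(g, "home_days"), 26.52)
})

test_that("home production is valued at replacement cost", {
  expect_equal(value_home_production(1, hours = 4, rate = 25), 100)
  expect_equal(value_home_production(0, hours = 4, rate = 25), 0)
  expect_error(value_home_production(1, hours = 4, rate = -1),
               class = "inactcost_validation_error")
  expect_error(value_home_production(-1, hours = 4, rate = 25),
               class = "inactcost_validation_error")
})

test_that("leisure is valued at a third of weekly earnings per standard week", {
  expect_equal(
    value_leisure(1, hours = 5, weekly_earnings = 1140,
                  standard_weekly_hours = 38),
    50)
  expect_equal(value_leisure(0, hours = 5, weekly_earnings = 1140,
                             standard_weekly_hours = 38), 0)
  expect_error(value_leisure(1, hours = 5, weekly_earnings = 1140,
                             standard_weekly_hours = 0),
               class = "inactcost_config_error")
})

test_that("unpaid values are degree-1 homogeneous in days and rates", {
  b <- default_bundle()
  g <- unpaid_day_gains(avert_burden(b$burden, feasible()), b$labor,
                        b$economics, feasible())
  v1 <- value_home_production(g, b$timeuse, b$params)
  g2 <- g
  g2$days <- 2 * g2$days
  expect_equal(value_home_production(g2, b$timeuse, b$params), 2 * v1)
  p2 <- b$params
  p2$replacement_rate_domestic <- 2 * p2$replacement_rate_domestic
  p2$replacement_rate_childcare <- 2 * p2$replacement_rate_childcare
  expect_equal(value_home_production(g, b$timeuse, p2), 2 * v1)
  l1 <- value_leisure(g, b$timeuse, b$economics, b$params)
  e2 <- b$economics
  e2$weekly_earnings <- 2 * e2$weekly_earnings
  expect_equal(value_leisure(g, b$timeuse, e2, b$params), 2 * l1)
})

test_that("values equal days x hours x unit price stratum-by-stratum", {
  b <- default_bundle()
  g <- unpaid_day_gains(avert_burden(b$burden, feasible()), b$labor,
                        b$economics, feasible())
  joined <- dplyr::left_join(g, b$timeuse,
                             by = c("sex", "age_band", "workforce"))
  rate <- (1 - b$params$childcare_weight) * b$params$replacement_rate_domestic +
    b$params$childcare_weight * b$params$replacement_rate_childcare
  expect_equal(value_home_production(g, b$timeuse, b$params),
               sum(joined$days * joined$household_hours * rate))
  joined <- dplyr::left_join(joined,
                             b$economics[c("sex", "age_band",
                                           "weekly_earnings")],
                             by = c("sex", "age_band"))
  expect_equal(value_leisure(g, b$timeuse, b$economics, b$params),
               sum(joined$days * joined$leisure_hours *
                     (joined$weekly_earnings / 3) /
                     b$params$standard_weekly_hours))
})

test_that("total model production is the exact sum of its components", {
  b <- default_bundle()
  for (target in c("feasible", "progressive")) {
    g <- glance(run_scenario(b, scenario_spec(target)))
    expect_equal(g$total_production_model,
                 g$workforce_production + g$home_production +
                   g$leisure_production,
                 tolerance = 1e-12)
  }
})
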