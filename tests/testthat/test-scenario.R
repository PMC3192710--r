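test_that("proportional impact fraction matches hand arithmetic", {
  expect_equal(impact_fraction(0.70, 0.10), 1 / 7)
  expect_equal(impact_fraction(0.70, 0), 0)
  expect_equal(impact_fraction(0.70, 0.70), 1)
})

test_that("PIF route matches the PAF-difference oracle", {
  # independent oracle: PAF(0.7, rr=2) = 0.7/1.7, PAF(0.6, rr=2) = 0.6/1.6
  paf <- function(p, rr) p * (rr - 1) / (1 + p * (rr - 1))
  oracle <- (paf(0.7, 2) - paf(0.6, 2)) / paf(0.7, 2)
  expect_equal(impact_fraction(0.70, 0.10, "pif", rr = 2), oracle,
               tolerance = 1e-12)
  expect_equal(oracle, 0.0892857142857, tolerance = 1e-10)
  expect_equal(impact_fraction(0.70, 0, "pif", rr = 2), 0)
})

test_that("impact fraction is monotone, bounded, and ordered across methods", {
  deltas <- seq(0, 0.7, by = 0.05)
  f <- vapply(deltas, function(d) impact_fraction(0.7, d), numeric(1))
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0 & f <= 1))
  for (rr in c(1.2, 1.6, 2, 5)) {
    expect_lt(impact_fraction(0.7, 0.1, "pif", rr = rr),
              impact_fraction(0.7, 0.1, "proportional"))
  }
  # convergence to the proportional fraction as rr -> 1+
  expect_equal(impact_fraction(0.7, 0.1, "pif", rr = 1 + 1e-8),
               impact_fraction(0.7, 0.1, "proportional"), tolerance = 1e-6)
})

test_that("impact fraction rejects out-of-domain input", {
  expect_error(impact_fraction(0.7, 0.8), class = "inactcost_domain_error")
  expect_error(impact_fraction(0.7, 0.1, "pif"),
               class = "inactcost_config_error")
  expect_error(impact_fraction(0.7, 0.1, "pif", rr = 0.5),
               class = "inactcost_domain_error")
})

test_that("averted burden reproduces the headline reductions", {
  b <- default_bundle()
  red <- avert_burden(b$burden, feasible())
  g <- glance(red)
  expect_equal(g$averted_cases, 45000 / 7, tolerance = 1e-9)   # 6,428.6
  expect_equal(g$averted_deaths, 13000 / 7, tolerance = 1e-9)  # 1,857.1
  expect_equal(g$averted_dalys, 174000 / 7, tolerance = 1e-9)  # 24,857
  expect_true(all(red$averted_cases >= 0 &
                    red$averted_cases <= b$burden$cases))
  expect_true(all(red$averted_dalys <= b$burden$dalys))
})

test_that("averted burden is linear in the prevalence shift", {
  b <- default_bundle()
  r10 <- avert_burden(b$burden, scenario_spec("feasible"))
  r5 <- avert_burden(b$burden, scenario_spec("progressive"))
  expect_equal(r5$averted_cases, r10$averted_cases / 2, tolerance = 1e-12)
  expect_equal(r5$averted_dalys, r10$averted_dalys / 2, tolerance = 1e-12)
  expect_equal(glance(r5)$averted_production_loss,
               glance(r10)$averted_production_loss / 2, tolerance = 1e-12)
})

test_that("elimination recovers the attributable table; null scenario zeroes it", {
  b <- default_bundle()
  elim <- avert_burden(b$burden, scenario_spec("elimination"))
  expect_equal(elim$averted_cases, b$burden$cases, tolerance = 1e-12)
  expect_equal(elim$averted_dalys, b$burden$dalys, tolerance = 1e-12)
  none <- avert_burden(b$burden, scenario_spec("custom", delta_pp = 0))
  expect_true(all(none$averted_cases == 0))
  expect_true(all(none$averted_dalys == 0))
})

test_that("PIF method applies per-disease relative risks", {
  b <- default_bundle()
  red <- avert_burden(b$burden, scenario_spec("feasible", method = "pif"))
  by_disease <- tapply(red$averted_cases / b$burden$cases, b$burden$disease,
                       function(x) mean(x[is.finite(x)]))
  rrs <- tapply(b$burden$relative_risk, b$burden$disease, unique)
  f_expected <- vapply(rrs, function(rr)
    impact_fraction(0.7, 0.1, "pif", rr = rr), numeric(1))
  expect_equal(as.numeric(by_disease), as.numeric(f_expected),
               tolerance = 1e-9)
})

test_that("avert_burden validates input and spec presets are correct", {
  expect_error(avert_burden(tibble::tibble(), feasible()),
               class = "inactcost_validation_error")
  expect_equal(scenario_spec("feasible")$delta_pp, 0.10)
  expect_equal(scenario_spec("progressive")$delta_pp, 0.05)
  expect_equal(scenario_spec("elimination")$delta_pp, 0.70)
  expect_error(scenario_spec("custom"), class = "inactcost_config_error")
  expect_error(scenario_spec("custom", delta_pp = 0.9),
               class = "inactcost_validation_error")
})
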