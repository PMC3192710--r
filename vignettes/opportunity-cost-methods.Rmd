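---
title: "Methods: scenario modelling of the opportunity cost of physical inactivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scenario modelling of the opportunity cost of physical inactivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inactcost)
```

## The question and the comparison

`inactcost` estimates what an adult population would gain if the prevalence
of physical inactivity fell by an absolute number of percentage points. The
comparator groups are the *exposed* (sedentary or low-activity) and
*non-exposed* (sufficiently active) subpopulations; a scenario moves a slice
of the population from the exposed to the non-exposed group and asks what
burden and costs follow. Three presets are built in: a feasible target
(10 points off the 70% baseline), a progressive target (5 points), and
elimination (the full 70 points, a theoretical-minimum comparison). People
who shift are assumed to adopt non-exposed disease and days-out-of-role
rates immediately; no time lag of benefit accrual is modelled.

## Impact fraction

The default method is **proportional**: averted attributable burden is
`f = Δp/p₀` of the attributable total. We label this choice *inferred*: it
is the only reading under which the published headline reductions are
mutually consistent (6/45 ≈ 2/13 ≈ 25/174 ≈ 96/672 ≈ 1/7 = 0.10/0.70), and
it treats the "10% reduction" as an absolute 10-percentage-point shift
(70% → 60%), consistent with the described sensitivity framing of "5% and
10% point shifts in prevalence". A **potential impact fraction** method is
provided as a documented alternative: with
`PAF(p) = p(RR−1)/(1+p(RR−1))`, `f = [PAF(p₀)−PAF(p₁)]/PAF(p₀)`. For RR > 1
it is strictly smaller than the proportional fraction and converges to it
as RR → 1; under the proportional method nothing depends on whether
disease-specific fractions are applied before or after summing, which is
why the choice is immaterial for the headline results.

## Valuation strands and their parameters

**Health sector.** Savings are one year's attributable treatment cost
scaled by `f`. This is deliberately annual: lifetime health-expenditure
modelling (including death-related cost offsets) is out of scope, so
savings are bounded by one year's attributable cost. The share of total
system cost divides by a total derived from the attributable-is-1.3%
statement (`total = attributable / 0.013`), overridable when a measured
total is available.

**Paid production.** Averted working-age (< 65) deaths map one-to-one to
workforce-exit events; permanent-disability exits and early retirements are
fractions of averted working-age incident cases (defaults 0.04 and 0.003).
These severity splits are fixture parameters — the sources publish none —
chosen once so that early retirements land in the published order of
magnitude (tens of persons under the feasible target). Under the **friction
cost approach** each averted exit saves
`weekly earnings × participation × friction_months × 52/12` weeks of wages
(13 weeks at the default 3 months; the week bridge is used because wage
tables are weekly) plus `recruitment_training_cost × participation`
(default AUD5,200 per replacement, a 2008-plausible hiring/training cost).
Under the **human capital approach** each exit saves all future income to
age 65, discounted end-of-year; recruitment costs do not arise. Absenteeism
gains — participation of the non-exposed stratum times the annualized
exposed/non-exposed difference in fortnight days off work, accrued over
remaining working years and discounted — are valued at a fifth of weekly
earnings per day and added to production value. Taxation effects apply a
flat effective rate, default 0.17 (the FCA-implied ratio in the published
economic table); the HCA-implied rate there (≈ 0.087) differs, and a single
flat rate cannot match both — we keep one configurable rate and flag the
discrepancy rather than resolving it.

**Unpaid production and leisure.** On a day of ill-health-reduced activity
neither household duties nor leisure happen, so a gained day credits *both*
pools (the joint-loss assumption); the pools differ only in hours and unit
prices. Day gains per averted case or death are the annualized
exposed/non-exposed difference in fortnight days of reduced activity,
accrued over remaining life expectancy. Home days are valued at replacement
cost: stratum household hours/day × a blended commercial rate (default 75%
domestic services at AUD31/h, 25% child care at AUD19/h, 2008 prices).
Leisure days are valued by the opportunity-cost method at one third of
average weekly earnings, bridged to an hourly price by a 38-hour standard
week.

**Discounting.** All lifetime streams — monetary values *and* day counts —
are discounted at the default 3%/yr with end-of-year timing (stated
explicitly because the source convention is unknown; sensitivities 0, 5,
7%). Discounting day counts keeps the published value = days × unit-price
identity exact within the model; discounting only money would break it.

## The synthetic-data generator

The generator emulates four restricted sources: a national health survey
(population, participation, days out of role, by sex × age × activity
status, with survey CIs), burden-of-disease files (attributable incident
cases, deaths, DALYs by disease × sex × age), disease-cost files
(attributable annual health-sector cost), and a time-use survey (household
and leisure hours/day). Design choices:

* **Age bands** are 5-year bands 15–19 … 85+; published groupings (15–64,
  65+) are derived aggregates, so one fixture serves every stage.
* **Group anchors are exact, within-band structure is synthetic.** The
  published group totals, participation and day rates enter unchanged (the
  15+ inactive share implied by the printed totals is 0.696, inside the
  ±0.005 band around 70%); the unpublished allocation across 5-year bands
  uses smooth demographic shapes with a small seeded lognormal jitter
  (sd 0.05), so different seeds give different but invariant-satisfying
  bundles while stratum *means* stay at their printed values (e.g. 0.32 vs
  0.26 days off work for inactive vs active working males, exactly).
* **Standard errors** come from printed 95% CIs as `(upper−lower)/3.92`.
* **Diseases** are the six named categories with DALY shares 51/20/14% for
  ischemic heart disease, type 2 diabetes and stroke, the remaining 15%
  split evenly; the same shares apply to cases, deaths, costs (an
  assumption, flagged in the manifest). Relative risks (1.3–1.6) are
  field-typical values used only by the PIF method. The within-disease
  age/sex distribution is assumed (older-skewed for chronic disease,
  younger-skewed for depression) and flagged in the manifest.
* **Calibration** rescales each burden column multiplicatively to the
  printed national totals (45,000 cases, 13,000 deaths, 174,000 DALYs,
  AUD672M health cost, AUD1,135M production losses) — exact, idempotent,
  and share-preserving. Attributable production losses are carried as a
  burden-table column allocated proportionally to DALYs, so the aggregate
  production headline is an arithmetic consequence of calibration.
* **Day rates stay per fortnight** in the fixture, as surveyed;
  annualization (×26) happens downstream only.

What the generator does *not* emulate: survey weighting and design effects,
within-band heterogeneity, correlation between inputs (none is published;
draws are independent), comorbidity between the six diseases, and the true
micro-distribution that produced the published lifetime day counts and the
workforce/home/leisure component split. Consequently passing tests show the
pipeline's arithmetic, calibration and orderings are right — not that the
synthetic micro-structure matches the confidential data. The bottom-up
component estimates (`workforce_production`, `home_production`,
`leisure_production`, day counts) therefore differ from the published
component split; they are reported alongside the calibrated aggregate
(`attributable_production_savings`), never forced to match it.

One documented deviation: we considered calibrating time-use hours and
rates so the model reproduces the published per-day aggregate values
(≈AUD394/home-day, ≈AUD250/leisure-day). That is infeasible under the
model's own pricing rules — at a realistic 2008 average weekly earnings
(≈AUD1,140) the leisure price is ≈AUD10/h, so AUD250/day would require
25 leisure hours/day, violating the 24-hour time-budget invariant. We keep
realistic wages, rates and hours and accept that the per-day aggregates are
not reproducible without the unpublished microdata.

## Uncertainty analysis

Every input with a survey SE — population counts, participation, days off
work, days of reduced activity, weekly earnings — is drawn from an
independent normal centred on its point value, truncated at zero
(proportions clipped to one); SE = 0 leaves a value untouched. The full
pipeline reruns per draw; results are summarised by the Monte Carlo mean
and percentile (not normal-approximation) 2.5/97.5 intervals, with the
unperturbed point estimate and the seed recorded alongside. The default
4,000 draws complete in under a minute on one core; attributable burden
totals carry no published SE, so burden-driven quantities (averted counts,
health savings) are degenerate in the uncertainty analysis — matching the
"n/a" interval entries in the published tables.

## Numerical conventions and degenerate inputs

Annuities use end-of-year discounting with pro-rata weight for a trailing
fraction of a year; a non-positive horizon contributes zero (so events at
or beyond age 65 have zero working-life value by construction, not by
error). Rounding for report is half-up — counts to the nearest thousand,
money to the nearest AUD million, percentages to integer (or two decimals
below 1%) — because half-up reproduces the published figures (24,857 →
25,000; 162.14 → 162) where banker's rounding would not. Zero-Δp scenarios,
empty event sets and zero-SE bundles all return exact zeros/fixed points
and are tested as such. Currency conversion divides by a purchasing-power
parity of 1.48 AUD/USD.

Recruitment/training costs are reported as a separate line and *excluded*
from the total-production aggregate: the published component sum
(12 + 71 + 79 = 162) excludes the recruitment line, and we follow that
reading while keeping the line visible.

## Problem sizes

The shipped fixture has 60 population strata (2 sexes × 15 bands × 2
statuses) and 180 burden rows (6 diseases × 2 sexes × 15 bands). Test-suite
Monte Carlo checks use 20–150 draws for structural properties and a single
4,000-draw run for the mean-convergence check; the generator property tests
sweep five seeds. These sizes were chosen as the smallest that exercise
every stratum and distributional property.

## Known limitations

Causality is taken from the attributable-burden inputs (cross-sectional,
self-reported exposure); no intervention costs or effectiveness, no benefit
lag, no labor-market equilibrium or wage growth, no multi-risk-factor joint
attribution, and no lifetime health-expenditure modelling. Opportunity-cost
savings are resources potentially redirectable, not realizable cash.
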