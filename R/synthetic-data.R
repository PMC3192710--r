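#' Generate a synthetic input bundle
#'
#' Builds the complete set of input tables the opportunity-cost pipeline
#' needs — population counts, labour-force and days-out-of-role profiles,
#' attributable disease burden, time use, and economic parameters — with the
#' statistical structure of the national survey and burden-of-disease sources
#' they emulate. Group-level anchors (stratum totals, participation and
#' day rates with their survey CIs) are taken from the named calibration
#' profile and held exactly; the allocation *within* 5-year age bands, which
#' the sources do not publish, is drawn with a small seeded lognormal jitter
#' so that different seeds give different (but always invariant-satisfying)
#' bundles.
#'
#' The returned bundle is calibrated so that national attributable totals
#' equal the profile's default targets (45,000 incident cases/yr, 13,000
#' deaths/yr, 174,000 DALYs/yr, AUD672 million/yr health-sector cost,
#' AUD1,135 million attributable production-and-leisure losses) exactly; see
#' [calibrate_to_totals()].
#'
#' @param seed Non-negative integer; the bundle is byte-identical for a fixed
#'   `(seed, profile)` pair.
#' @param profile Name of a packaged calibration profile; see
#'   [calibration_profiles()]. Default `"table1_default"`.
#' @param calibrate If `TRUE` (default), calibrate burden totals to the
#'   profile's default targets.
#'
#' @return An object of class `inact_bundle`: a list of tibbles
#'   `population`, `labor`, `burden`, `timeuse`, `economics`, a list
#'   `params` of scalar economic/model parameters, and `meta` (seed, profile,
#'   calibration targets, assumption flags).
#' @export
#' @examples
#' b <- generate_inputs(seed = 2008)
#' b$population
#' dplyr::summarise(b$burden, cases = sum(cases), dalys = sum(dalys))
generate_inputs <- function(seed, profile = "table1_default", calibrate = TRUE) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed < 0 || seed != trunc(seed)) {
    abort("`seed` must be a single non-negative integer.",
          class = "inactcost_validation_error")
  }
  profiles <- calibration_profiles()
  if (!is.character(profile) || length(profile) != 1L ||
      !profile %in% names(profiles)) {
    abort(sprintf("Unknown calibration profile %s; available: %s.",
                  deparse(profile), paste(names(profiles), collapse = ", ")),
          class = "inactcost_config_error")
  }
  prof <- profiles[[profile]]

  bundle <- with_seed(as.integer(seed), build_bundle(prof))
  bundle$meta <- list(
    seed = as.integer(seed),
    profile = profile,
    targets = NULL,
    assumptions = c(
      "within-band age allocation is synthetic (sources publish group totals only)",
      "within-disease age/sex distribution of attributable burden is assumed"
    )
  )
  class(bundle) <- "inact_bundle"
  if (calibrate) {
    bundle <- calibrate_to_totals(bundle, prof$default_targets)
  }
  bundle
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

build_bundle <- function(prof) {
  bands <- age_bands()
  grp <- age_group_of(bands)
  jsd <- prof$params$allocation_jitter_sd

  # --- population: spread each group total over its bands ------------------
  spread_group <- function(total, se, which_bands, shape) {
    w <- shape * exp(rnorm(length(shape), 0, jsd))
    w <- w / sum(w)
    tibble::tibble(age_band = which_bands, count = total * w, count_se = se * w)
  }
  population <- prof$population |>
    dplyr::mutate(se = (.data$hi - .data$lo) / 3.92) |>
    purrr::pmap(function(sex, age_group, activity, count, lo, hi, se) {
      b <- bands[grp == age_group]
      shape <- if (age_group == "15-64") prof$age_shapes$pop_1564
               else prof$age_shapes$pop_65p
      dplyr::mutate(spread_group(count, se, b, shape),
                    sex = sex, activity = activity)
    }) |>
    purrr::list_rbind() |>
    dplyr::select("sex", "age_band", "activity", "count", "count_se") |>
    dplyr::arrange(.data$sex, match(.data$age_band, bands), .data$activity)

  # --- labour profile ------------------------------------------------------
  part <- prof$participation |>
    dplyr::mutate(p_se = (.data$hi - .data$lo) / 3.92) |>
    dplyr::select("sex", "age_group", "activity", in_labor_force = "p", in_labor_force_se = "p_se")
  doff <- prof$days_off |>
    dplyr::mutate(d_se = (.data$hi - .data$lo) / 3.92) |>
    dplyr::select("sex", "activity", days_off_work = "d", days_off_work_se = "d_se")
  dred <- prof$days_reduced |>
    dplyr::mutate(d_se = (.data$hi - .data$lo) / 3.92) |>
    dplyr::select("sex", "age_group", "activity",
                  days_reduced_activity = "d", days_reduced_activity_se = "d_se")

  labor <- tidyr::expand_grid(
    sex = c("male", "female"), age_band = bands,
    activity = c("exposed", "non_exposed")
  ) |>
    dplyr::mutate(age_group = age_group_of(.data$age_band)) |>
    dplyr::left_join(part, by = c("sex", "age_group", "activity")) |>
    dplyr::left_join(doff, by = c("sex", "activity")) |>
    dplyr::left_join(dred, by = c("sex", "age_group", "activity")) |>
    dplyr::select(-"age_group")

  # --- attributable burden -------------------------------------------------
  base <- prof$default_targets
  p0 <- prof$params$baseline_prevalence
  burden <- prof$diseases |>
    purrr::pmap(function(disease, share, relative_risk, male_share, age_shape) {
      shape <- prof$age_shapes[[age_shape]]
      w_case <- shape * exp(rnorm(length(shape), 0, jsd))
      w_case <- w_case / sum(w_case)
      # deaths skew older than incidence within the same disease shape
      w_death <- w_case * seq(0.3, 2, length.out = length(shape))
      w_death <- w_death / sum(w_death)
      tidyr::expand_grid(sex = c("male", "female"), age_band = bands) |>
        dplyr::mutate(
          disease = disease,
          sshare = ifelse(.data$sex == "male", male_share, 1 - male_share),
          wc = rep(w_case, times = 2),
          wd = rep(w_death, times = 2),
          cases = base[["cases"]] * share * .data$sshare * .data$wc,
          deaths = base[["deaths"]] * share * .data$sshare * .data$wd,
          dalys = base[["dalys"]] * share * .data$sshare * .data$wc,
          health_cost = base[["health_cost"]] * share * .data$sshare * .data$wc,
          production_loss = base[["production_loss"]] * share * .data$sshare * .data$wc,
          relative_risk = relative_risk,
          paf = p0 * (relative_risk - 1) / (1 + p0 * (relative_risk - 1))
        ) |>
        dplyr::select("disease", "sex", "age_band", "cases", "deaths", "dalys",
                      "health_cost", "production_loss", "relative_risk", "paf")
    }) |>
    purrr::list_rbind()

  # --- time use ------------------------------------------------------------
  timeuse <- tidyr::expand_grid(
    sex = c("male", "female"), age_band = bands, workforce = c("in", "out")
  ) |>
    dplyr::left_join(prof$timeuse, by = c("sex", "workforce"))

  # --- per-stratum economics ----------------------------------------------
  mids <- age_band_midpoint(bands)
  economics <- tidyr::expand_grid(sex = c("male", "female"), age_band = bands) |>
    dplyr::mutate(
      idx = match(.data$age_band, bands),
      weekly_earnings = unname(prof$wages$peak[.data$sex]) *
        prof$wages$profile[.data$idx],
      weekly_earnings_se = prof$wages$rel_se * .data$weekly_earnings,
      remaining_life_expectancy = purrr::map2_dbl(
        .data$sex, .data$idx, ~ prof$life_expectancy[[.x]][.y]),
      remaining_working_years = pmin(
        pmax(0, prof$params$retirement_age - mids[.data$idx]),
        .data$remaining_life_expectancy)
    ) |>
    dplyr::select(-"idx")

  list(population = population, labor = labor, burden = burden,
       timeuse = timeuse, economics = economics, params = prof$params)
}

#' Calibrate a bundle's burden tables to national totals
#'
#' Rescales each attributable quantity of the burden table multiplicatively,
#' preserving its disease/sex/age shares exactly, so that national totals
#' equal the supplied targets. Idempotent: calibrating twice to the same
#' targets changes nothing.
#'
#' @param bundle An `inact_bundle` from [generate_inputs()].
#' @param targets Named numeric vector of national annual totals; any subset
#'   of `cases`, `deaths`, `dalys`, `health_cost`, `production_loss`
#'   (monetary targets in AUD/yr).
#' @return The calibrated bundle (inputs are not mutated).
#' @export
#' @examples
#' b <- generate_inputs(2008)
#' b2 <- calibrate_to_totals(b, c(cases = 45000, dalys = 174000))
#' sum(b2$burden$cases)
calibrate_to_totals <- function(bundle,
                                targets = c(cases = 45000, deaths = 13000,
                                            dalys = 174000, health_cost = 672e6,
                                            production_loss = 1135e6)) {
  stopifnot(inherits(bundle, "inact_bundle") || is.list(bundle))
  if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
    abort("`targets` must be a named numeric vector.",
          class = "inactcost_validation_error")
  }
  bad <- setdiff(names(targets), c("cases", "deaths", "dalys",
                                   "health_cost", "production_loss"))
  if (length(bad)) {
    abort(sprintf("Unknown calibration target(s): %s.",
                  paste(bad, collapse = ", ")),
          class = "inactcost_validation_error")
  }
  if (any(!is.finite(targets)) || any(targets < 0)) {
    abort("Calibration targets must be non-negative finite numbers.",
          class = "inactcost_validation_error")
  }
  burden <- bundle$burden
  for (nm in names(targets)) {
    tot <- sum(burden[[nm]])
    if (tot == 0) {
      if (targets[[nm]] > 0) {
        abort(sprintf("Cannot calibrate `%s`: table sums to zero but target is %g.",
                      nm, targets[[nm]]),
              class = "inactcost_calibration_error")
      }
      next
    }
    burden[[nm]] <- burden[[nm]] * (targets[[nm]] / tot)
  }
  bundle$burden <- burden
  bundle$meta$targets <- as.list(targets)
  bundle
}

#' Validate an input bundle's invariants
#'
#' Checks non-negativity of counts, rates and money; exposure shares in
#' `[0,1]`; day rates within the two-week recall window; PAFs in `[0,1)`;
#' time-use hours summing to at most 24 h/day; and remaining working years
#' not exceeding remaining life expectancy. Errors (class
#' `inactcost_validation_error`) on the first violation.
#'
#' @param bundle An `inact_bundle`.
#' @return `bundle`, invisibly, if valid.
#' @export
validate_bundle <- function(bundle) {
  fail <- function(msg) abort(msg, class = "inactcost_validation_error")
  p <- bundle$population
  if (any(p$count < 0) || any(p$count_se < 0)) fail("negative population count or SE")
  shares <- p |>
    tidyr::pivot_wider(id_cols = c("sex", "age_band"), names_from = "activity",
                       values_from = "count") |>
    dplyr::mutate(s = .data$exposed / (.data$exposed + .data$non_exposed))
  if (any(shares$s < 0 | shares$s > 1)) fail("exposure share outside [0,1]")
  l <- bundle$labor
  if (any(l$in_labor_force < 0 | l$in_labor_force > 1)) fail("participation outside [0,1]")
  if (any(l$days_off_work < 0 | l$days_off_work > 14) ||
      any(l$days_reduced_activity < 0 | l$days_reduced_activity > 14)) {
    fail("day rate outside the [0,14] fortnight window")
  }
  b <- bundle$burden
  num <- c("cases", "deaths", "dalys", "health_cost", "production_loss")
  if (any(as.matrix(b[num]) < 0)) fail("negative attributable quantity")
  if (any(b$paf < 0 | b$paf >= 1)) fail("PAF outside [0,1)")
  if (any(b$relative_risk < 1)) fail("relative risk below 1")
  tu <- bundle$timeuse
  if (any(tu$household_hours < 0) || any(tu$leisure_hours < 0) ||
      any(tu$household_hours + tu$leisure_hours > 24)) {
    fail("time-use hours negative or exceeding 24 h/day")
  }
  e <- bundle$economics
  if (any(e$weekly_earnings < 0)) fail("negative weekly earnings")
  if (any(e$remaining_working_years > e$remaining_life_expectancy + 1e-9)) {
    fail("remaining working years exceed remaining life expectancy")
  }
  invisible(bundle)
}

#' National inactivity prevalence of a bundle
#'
#' Share of the 15+ population in the exposed (physically inactive) stratum.
#'
#' @param bundle An `inact_bundle`.
#' @return A single number in `[0,1]`.
#' @export
inactivity_prevalence <- function(bundle) {
  p <- bundle$population
  sum(p$count[p$activity == "exposed"]) / sum(p$count)
}

#' @export
print.inact_bundle <- function(x, ...) {
  cat("<inact_bundle>",
      sprintf("seed %d, profile '%s'%s", x$meta$seed, x$meta$profile,
              if (length(x$meta$targets)) ", calibrated" else ""), "\n")
  cat(sprintf("  population: %d strata (15+ inactivity prevalence %.3f)\n",
              nrow(x$population), inactivity_prevalence(x)))
  cat(sprintf("  burden: %d disease x sex x age rows; %s cases/yr, %s DALYs/yr\n",
              nrow(x$burden),
              format(round(sum(x$burden$cases)), big.mark = ","),
              format(round(sum(x$burden$dalys)), big.mark = ",")))
  cat(sprintf("  attributable health cost AUD%.0fM/yr; production losses AUD%.0fM\n",
              sum(x$burden$health_cost) / 1e6,
              sum(x$burden$production_loss) / 1e6))
  invisible(x)
}

#' Write / read a bundle as a directory of CSV tables
#'
#' Serializes the five input tables to `population.csv`, `labor.csv`,
#' `burden.csv`, `timeuse.csv`, `economics.csv` plus a `manifest.yaml`
#' recording the seed, profile, calibration targets, scalar parameters and
#' assumption flags. Money is in 2008 AUD, day rates per fortnight, time use
#' in hours/day.
#'
#' @param bundle An `inact_bundle`.
#' @param dir Directory to write to (created if missing).
#' @return `write_bundle()`: `dir`, invisibly. `read_bundle()`: the bundle.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("population", "labor", "burden", "timeuse", "economics")
  for (nm in tables) {
    write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  yaml::write_yaml(
    list(seed = bundle$meta$seed, profile = bundle$meta$profile,
         targets = bundle$meta$targets, params = bundle$params,
         assumptions = as.list(bundle$meta$assumptions)),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  tables <- c("population", "labor", "burden", "timeuse", "economics")
  bundle <- purrr::map(
    setNames(tables, tables),
    ~ tibble::as_tibble(read.csv(file.path(dir, paste0(.x, ".csv")),
                                 stringsAsFactors = FALSE)))
  bundle$params <- man$params
  bundle$meta <- list(seed = man$seed, profile = man$profile,
                      targets = man$targets,
                      assumptions = unlist(man$assumptions))
  class(bundle) <- "inact_bundle"
  bundle
}
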