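#' Run the full opportunity-cost pipeline for one scenario
#'
#' Chains every stage on a calibrated input bundle: impact fraction and
#' averted burden, annual health-sector savings, workforce-exit events and
#' paid-production valuation (FCA or HCA per the spec), lifetime absenteeism
#' gains, and unpaid household-production and leisure valuation. Two
#' production aggregates are reported:
#'
#' * `attributable_production_savings` — the impact fraction applied to the
#'   bundle's calibrated national attributable production-and-leisure losses
#'   (the aggregate accounting used for headline totals);
#' * `total_production_model` — the bottom-up cohort model's sum
#'   (workforce production + home production + leisure), which depends on
#'   the synthetic micro-structure and is reported alongside, not forced to
#'   match the aggregate.
#'
#' @param bundle A calibrated `inact_bundle`.
#' @param spec A [scenario_spec()].
#' @return A `scenario_result` tibble with columns `quantity`, `value`,
#'   `units`; attributes `spec` and `valuation`. [glance()] returns the
#'   quantities as a one-row wide tibble.
#' @export
#' @examples
#' res <- run_scenario(generate_inputs(2008), scenario_spec("feasible"))
#' glance(res)$health_savings
run_scenario <- function(bundle, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  averted <- avert_burden(bundle$burden, spec)
  tot <- attr(averted, "totals")

  health <- health_cost_savings(sum(bundle$burden$health_cost) / 1e6, spec)

  absent <- absenteeism_gain(averted, bundle$labor, bundle$economics, spec)
  events <- derive_exit_events(averted, bundle$params)
  prod <- if (spec$valuation == "FCA") {
    fca_value(events, bundle$labor, bundle$economics, bundle$params, spec,
              absenteeism = absent)
  } else {
    hca_value(events, bundle$labor, bundle$economics, bundle$params, spec,
              absenteeism = absent)
  }

  unpaid <- unpaid_day_gains(averted, bundle$labor, bundle$economics, spec)
  home_value <- value_home_production(unpaid, bundle$timeuse, bundle$params)
  leisure_value <- value_leisure(unpaid, bundle$timeuse, bundle$economics,
                                 bundle$params)

  attributable_prod <- tot[["averted_production_loss"]] / 1e6
  total_model <- prod$production_value + home_value / 1e6 + leisure_value / 1e6

  days_unit <- "days (lifetime, discounted)"
  out <- tibble::tibble(
    quantity = c("averted_cases", "averted_deaths", "averted_dalys",
                 "health_savings", "health_share_attributable",
                 "health_share_total_system", "absenteeism_days",
                 "workforce_production", "taxation", "recruitment_training",
                 "early_retirements_averted", "home_days", "leisure_days",
                 "home_production", "leisure_production",
                 "total_production_model", "attributable_production_savings",
                 "grand_total_savings"),
    value = c(tot[["averted_cases"]], tot[["averted_deaths"]],
              tot[["averted_dalys"]], health$savings,
              health$share_of_attributable, health$share_of_total_system,
              prod$absenteeism_days, prod$production_value,
              prod$taxation_value, prod$recruitment_training_value,
              prod$early_retirements_averted, attr(unpaid, "home_days"),
              attr(unpaid, "leisure_days"), home_value / 1e6,
              leisure_value / 1e6, total_model, attributable_prod,
              health$savings + attributable_prod),
    units = c("cases/yr", "deaths/yr", "DALYs/yr", "AUD million/yr",
              "fraction", "fraction", days_unit, "AUD million",
              "AUD million", "AUD million", "persons", days_unit, days_unit,
              "AUD million", "AUD million", "AUD million", "AUD million",
              "AUD million")
  )
  structure(out, spec = spec, valuation = spec$valuation,
            class = c("scenario_result", class(out)))
}

#' @export
tidy.scenario_result <- function(x, ...) {
  out <- x
  attributes(out)[c("spec", "valuation")] <- NULL
  class(out) <- setdiff(class(out), "scenario_result")
  tibble::as_tibble(out)
}

#' @export
glance.scenario_result <- function(x, ...) {
  tibble::as_tibble(as.list(setNames(x$value, x$quantity)))
}

#' @export
print.scenario_result <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("<scenario_result> %s target, %s method, %s valuation\n",
              spec$target, spec$method, spec$valuation))
  NextMethod()
}

#' Opportunity-cost category shares
#'
#' Breakdown of total monetary savings into the reporting categories
#' (health sector, workforce production, taxation, recruitment/training,
#' home-based and leisure-based production), with percentage shares that sum
#' to 100.
#'
#' @param result A [run_scenario()] result.
#' @return A tibble: `category`, `value` (AUD million), `share_pct`.
#' @export
category_shares <- function(result) {
  g <- glance(result)
  cats <- tibble::tibble(
    category = c("health_sector", "workforce_production", "taxation",
                 "recruitment_training", "home_production",
                 "leisure_production"),
    value = c(g$health_savings, g$workforce_production, g$taxation,
              g$recruitment_training, g$home_production, g$leisure_production)
  )
  dplyr::mutate(cats, share_pct = 100 * .data$value / sum(.data$value))
}

#' Round a raw value to the reporting convention
#'
#' Counts are reported to the nearest thousand (in thousands); money to the
#' nearest AUD million; percentages to the printed precision (integer
#' percent at 1% and above, two decimals below 1%). Rounding is half-up,
#' which reproduces the published figures (24,857 -> 25 thousand;
#' 162.14 -> 162).
#'
#' @param value Raw value (counts in units, money in AUD million, percents
#'   in percentage points).
#' @param kind `"count"`, `"money"` or `"percent"`.
#' @return The reported value (thousands for counts).
#' @export
#' @examples
#' round_for_report(24857, "count")    # 25
#' round_for_report(162.14, "money")   # 162
#' round_for_report(0.1857, "percent") # 0.19
round_for_report <- function(value, kind = c("count", "money", "percent")) {
  kind <- match.arg(kind)
  if (!is.numeric(value) || any(!is.finite(value))) {
    abort("`value` must be finite.", class = "inactcost_validation_error")
  }
  switch(kind,
         count = round_half_up(value / 1000),
         money = round_half_up(value),
         percent = ifelse(abs(value) < 1, round_half_up(value, 2),
                          round_half_up(value)))
}

#' Convert 2008 AUD to USD at purchasing power parity
#'
#' @param aud Amount in AUD (vectorised).
#' @param ppp AUD per USD at purchasing power parity (default 1.48).
#' @return Amount in USD.
#' @export
#' @examples
#' convert_currency(1.48)  # 1
convert_currency <- function(aud, ppp = 1.48) {
  if (!is.numeric(ppp) || length(ppp) != 1L || !is.finite(ppp) || ppp <= 0) {
    abort("`ppp` must be a single positive number.",
          class = "inactcost_config_error")
  }
  aud / ppp
}

#' Format scenario results as a publication-style report table
#'
#' Mirrors the published layout: a health-status block (averted DALYs,
#' incident cases, deaths in thousands; lifetime day gains in thousands) and
#' an economic block (AUD million), with raw and rounded-for-report values.
#'
#' @param result A [run_scenario()] result (or a named list of them, one per
#'   scenario, which are stacked with a `scenario` column).
#' @return A tibble: `block`, `quantity`, `raw`, `reported`, `units`
#'   (plus `scenario` for a list input).
#' @export
report_table <- function(result) {
  if (is.list(result) && !inherits(result, "scenario_result")) {
    return(purrr::imap(result,
                       ~ dplyr::mutate(report_table(.x), scenario = .y,
                                       .before = 1)) |>
             purrr::list_rbind())
  }
  g <- glance(result)
  health_block <- tibble::tribble(
    ~quantity, ~raw, ~kind, ~units,
    "dalys_averted", g$averted_dalys, "count", "'000s/yr",
    "incident_cases_averted", g$averted_cases, "count", "'000s/yr",
    "deaths_averted", g$averted_deaths, "count", "'000s/yr",
    "leisure_days", g$leisure_days, "count", "'000s, lifetime",
    "absenteeism_days", g$absenteeism_days, "count", "'000s, lifetime",
    "home_production_days", g$home_days, "count", "'000s, lifetime",
    "early_retirements_averted", g$early_retirements_averted * 1000, "count",
    "'000s"
  ) |> dplyr::mutate(block = "health_status")
  econ_block <- tibble::tribble(
    ~quantity, ~raw, ~kind, ~units,
    "health_sector_costs", g$health_savings, "money", "AUD million",
    "production_costs", g$workforce_production, "money", "AUD million",
    "recruitment_training_costs", g$recruitment_training, "money", "AUD million",
    "taxation_effects", g$taxation, "money", "AUD million",
    "leisure_based_production", g$leisure_production, "money", "AUD million",
    "home_based_production", g$home_production, "money", "AUD million",
    "total_production", g$total_production_model, "money", "AUD million",
    "attributable_production_savings", g$attributable_production_savings,
    "money", "AUD million",
    "grand_total_savings", g$grand_total_savings, "money", "AUD million"
  ) |> dplyr::mutate(block = "economic")
  dplyr::bind_rows(health_block, econ_block) |>
    dplyr::mutate(reported = round_for_report(.data$raw, "count") *
                    (.data$kind == "count") +
                    round_for_report(.data$raw, "money") *
                    (.data$kind == "money")) |>
    dplyr::select("block", "quantity", "raw", "reported", "units")
}

#' Run the pipeline from a configuration file
#'
#' Reads a YAML (or JSON) configuration, generates and calibrates the input
#' bundle, runs every requested scenario, optionally runs the Monte Carlo
#' uncertainty analysis, and writes results (`results.csv`, `results.json`,
#' `report.csv`, `mc.csv` when drawn) plus a run manifest
#' (`manifest.yaml` with the config hash, seed and package version) to the
#' output directory. Progress is logged with [message()].
#'
#' Recognised config fields (defaults in parentheses): `seed` (2008),
#' `profile` (`"table1_default"`), `scenarios` (`"feasible"`), `method`
#' (`"proportional"`), `valuation` (`"FCA"`), `discount_rate` (0.03),
#' `friction_months` (3), `baseline_prevalence` (0.70), `n_draws` (0 = no
#' Monte Carlo), `mc_scenario` (first scenario), `targets` (profile
#' defaults).
#'
#' @param config Path to a YAML/JSON config file, or an equivalent named
#'   list.
#' @param out_dir Output directory (default `"inactcost-results"`; created).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `results` (tibble across scenarios),
#'   `report`, `mc` (or `NULL`), and `paths`.
#' @export
run_pipeline <- function(config, out_dir = "inactcost-results",
                         quiet = FALSE) {
  cfg <- load_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("generating inputs (seed %d, profile '%s')", cfg$seed, cfg$profile)
  bundle <- generate_inputs(cfg$seed, cfg$profile)
  if (!is.null(cfg$targets)) {
    bundle <- calibrate_to_totals(bundle, unlist(cfg$targets))
  }
  validate_bundle(bundle)

  specs <- setNames(lapply(cfg$scenarios, function(s) {
    scenario_spec(s, baseline_prevalence = cfg$baseline_prevalence,
                  method = cfg$method, discount_rate = cfg$discount_rate,
                  valuation = cfg$valuation,
                  friction_months = cfg$friction_months)
  }), cfg$scenarios)

  scenario_objects <- purrr::imap(specs, function(sp, nm) {
    say("running scenario '%s'", nm)
    run_scenario(bundle, sp)
  })
  results_tbl <- purrr::imap(scenario_objects,
                             ~ dplyr::mutate(tidy(.x), scenario = .y,
                                             .before = 1)) |>
    purrr::list_rbind()
  report <- report_table(scenario_objects)

  mc <- NULL
  if (cfg$n_draws > 0) {
    mc_scen <- cfg$mc_scenario %||% cfg$scenarios[[1]]
    say("Monte Carlo: %d draws on scenario '%s'", cfg$n_draws, mc_scen)
    mc <- run_monte_carlo(bundle, specs[[mc_scen]], n_draws = cfg$n_draws,
                          seed = cfg$seed)
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    results_csv = file.path(out_dir, "results.csv"),
    results_json = file.path(out_dir, "results.json"),
    report_csv = file.path(out_dir, "report.csv"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  write.csv(results_tbl, paths$results_csv, row.names = FALSE)
  jsonlite::write_json(
    purrr::map(scenario_objects, ~ as.list(setNames(.x$value, .x$quantity))),
    paths$results_json, auto_unbox = TRUE, digits = NA)
  write.csv(report, paths$report_csv, row.names = FALSE)
  if (!is.null(mc)) {
    paths$mc_csv <- file.path(out_dir, "mc.csv")
    mc_out <- dplyr::mutate(tidy(mc), n_draws = attr(mc, "n_draws"),
                            seed = attr(mc, "seed"))
    write.csv(mc_out, paths$mc_csv, row.names = FALSE)
  }
  yaml::write_yaml(
    list(config = cfg, config_hash = rlang::hash(cfg),
         package_version = as.character(utils::packageVersion("inactcost")),
         seed = cfg$seed),
    paths$manifest)
  say("wrote %s", out_dir)
  invisible(list(results = results_tbl, report = report, mc = mc,
                 paths = paths))
}

load_config <- function(config) {
  defaults <- list(
    seed = 2008L, profile = "table1_default",
    scenarios = "feasible", method = "proportional", valuation = "FCA",
    discount_rate = 0.03, friction_months = 3, baseline_prevalence = 0.70,
    n_draws = 0L, mc_scenario = NULL, targets = NULL
  )
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("Config file not found: %s", config),
            class = "inactcost_file_error")
    }
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) {
    abort("`config` must be a file path or a named list.",
          class = "inactcost_schema_error")
  }
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown config field(s): %s.",
                  paste0("$", unknown, collapse = ", ")),
          class = "inactcost_schema_error")
  }
  cfg <- modifyList(defaults, config, keep.null = TRUE)
  check <- function(ok, field, expect) {
    if (!ok) abort(sprintf("Config field $%s must be %s.", field, expect),
                   class = "inactcost_schema_error")
  }
  check(is.numeric(cfg$seed) && cfg$seed >= 0, "seed", "a non-negative integer")
  check(is.character(cfg$profile), "profile", "a profile name")
  check(is.character(cfg$scenarios) && length(cfg$scenarios) >= 1,
        "scenarios", "one or more scenario presets")
  check(is.numeric(cfg$n_draws) && cfg$n_draws >= 0, "n_draws",
        "a non-negative integer")
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_draws <- as.integer(cfg$n_draws)
  cfg
}
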