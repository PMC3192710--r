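#' Draw a perturbed input bundle
#'
#' Every input carrying a survey standard error — population counts,
#' labour-force participation, days off work, days of reduced activity,
#' weekly earnings — is redrawn from a normal distribution centred on its
#' point value with that SE, truncated at zero (proportions additionally
#' clipped to one). Quantities with `SE = 0` are returned unchanged, so a
#' zero-SE bundle is a fixed point. Inputs are assumed independent: the
#' sources publish no correlation structure.
#'
#' @param bundle An `inact_bundle`.
#' @param seed Optional integer; when supplied the draw is deterministic and
#'   the caller's RNG state is left untouched.
#' @return A perturbed copy of the bundle.
#' @export
draw_inputs <- function(bundle, seed = NULL) {
  if (!is.null(seed)) {
    return(with_seed(as.integer(seed), draw_inputs(bundle)))
  }
  b <- bundle
  tnorm <- function(mean, se, upper = Inf) {
    pmin(upper, pmax(0, rnorm(length(mean), mean, se)))
  }
  b$population$count <- tnorm(b$population$count, b$population$count_se)
  b$labor$in_labor_force <- tnorm(b$labor$in_labor_force,
                                  b$labor$in_labor_force_se, upper = 1)
  b$labor$days_off_work <- tnorm(b$labor$days_off_work,
                                 b$labor$days_off_work_se, upper = 14)
  b$labor$days_reduced_activity <- tnorm(b$labor$days_reduced_activity,
                                         b$labor$days_reduced_activity_se,
                                         upper = 14)
  b$economics$weekly_earnings <- tnorm(b$economics$weekly_earnings,
                                       b$economics$weekly_earnings_se)
  b
}

#' Monte Carlo uncertainty analysis of the full pipeline
#'
#' Repeatedly perturbs the uncertain inputs with [draw_inputs()], reruns the
#' whole scenario pipeline ([run_scenario()]) on each draw, and summarises
#' every reported quantity with its Monte Carlo mean and a percentile 95%
#' uncertainty interval (2.5th and 97.5th percentiles), alongside the
#' unperturbed point estimate.
#'
#' @param bundle An `inact_bundle`.
#' @param spec A [scenario_spec()].
#' @param n_draws Number of simulations; at least 4,000 is recommended (a
#'   warning is issued below that).
#' @param seed Integer seed governing all draws.
#' @return An `mc_result` tibble: `quantity`, `units`, `point`, `mc_mean`,
#'   `ui_lower`, `ui_upper`, with attributes `n_draws` and `seed`.
#' @export
run_monte_carlo <- function(bundle, spec, n_draws = 4000, seed = 1L) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.numeric(n_draws) || length(n_draws) != 1L || n_draws < 1) {
    abort("`n_draws` must be a positive integer.",
          class = "inactcost_config_error")
  }
  n_draws <- as.integer(n_draws)
  if (n_draws < 4000) {
    warn(sprintf("n_draws = %d is below the recommended minimum of 4,000.",
                 n_draws))
  }
  point <- run_scenario(bundle, spec)
  draws <- with_seed(as.integer(seed), {
    vapply(seq_len(n_draws),
           function(i) run_scenario(draw_inputs(bundle), spec)$value,
           numeric(nrow(point)))
  })
  draws <- matrix(draws, nrow = nrow(point))
  out <- tibble::tibble(
    quantity = point$quantity,
    units = point$units,
    point = point$value,
    mc_mean = rowMeans(draws),
    ui_lower = apply(draws, 1, quantile, probs = 0.025, names = FALSE),
    ui_upper = apply(draws, 1, quantile, probs = 0.975, names = FALSE)
  )
  structure(out, n_draws = n_draws, seed = as.integer(seed),
            spec = spec, class = c("mc_result", class(out)))
}

#' @export
tidy.mc_result <- function(x, ...) {
  out <- x
  attributes(out)[c("n_draws", "seed", "spec")] <- NULL
  class(out) <- setdiff(class(out), "mc_result")
  tibble::as_tibble(out)
}

#' @export
glance.mc_result <- function(x, ...) {
  tibble::tibble(n_draws = attr(x, "n_draws"), seed = attr(x, "seed"),
                 n_quantities = nrow(x))
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> %d draws, seed %d\n",
              attr(x, "n_draws"), attr(x, "seed")))
  NextMethod()
}
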