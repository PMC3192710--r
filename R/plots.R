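#' Plot the category breakdown of opportunity-cost savings
#'
#' Bar chart of the share of total monetary savings by economic category
#' (health sector, workforce production, taxation, recruitment/training,
#' home-based and leisure-based production).
#'
#' @param object A [run_scenario()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scenario_result <- function(object, ...) {
  shares <- category_shares(object)
  ggplot2::ggplot(shares,
                  ggplot2::aes(x = stats::reorder(.data$category,
                                                  -.data$share_pct),
                               y = .data$share_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Share of savings (%)",
                  title = "Opportunity-cost savings by category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot Monte Carlo uncertainty intervals
#'
#' Point estimates with 95% percentile uncertainty intervals for the
#' monetary quantities of an [run_monte_carlo()] result.
#'
#' @param object An `mc_result`.
#' @param units Which unit group to show (default AUD million quantities).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mc_result <- function(object, units = "AUD million", ...) {
  d <- dplyr::filter(tidy(object), .data$units == !!units)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$point, y = .data$quantity)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ui_lower,
                                          xmax = .data$ui_upper)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$mc_mean), shape = 1) +
    ggplot2::labs(x = units, y = NULL,
                  title = sprintf("95%% uncertainty intervals (%d draws)",
                                  attr(object, "n_draws"))) +
    ggplot2::theme_minimal()
}
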