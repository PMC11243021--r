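#' Plot actual and simulated weight over a simulated period
#'
#' Day 0 is the start of the (biohacked) diet; the actual recorded weights
#' and the avatar's simulated path under the counterfactual diet are
#' overlaid.
#'
#' @param sim A `pma_simulation` from [walk_forward_simulation()].
#' @param features The feature series the simulation ran on (for the actual
#'   weights).
#' @return A ggplot object.
#' @export
plot_weight_simulation <- function(sim, features) {
  idx <- match(sim$dates, features$date)
  df <- dplyr::bind_rows(
    tibble::tibble(day = seq_along(sim$path), weight_kg = features$weight[idx],
                   series = "actual"),
    tibble::tibble(day = seq_along(sim$path), weight_kg = sim$path,
                   series = "simulated (biohacked)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$weight_kg,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "day of period", y = "weight (kg)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot distributions of period weight changes
#'
#' Side-by-side distributions of actual versus simulated two-week weight
#' changes, per participant.
#'
#' @param results Named list of period tibbles (see
#'   [simulate_biohacked_periods()]) or a single tibble.
#' @return A ggplot object.
#' @export
plot_dw_distributions <- function(results) {
  if (is.data.frame(results)) results <- list(participant = results)
  df <- purrr::imap(results, function(res, id) {
    tibble::tibble(participant = id,
                   dw = c(res$dw_actual, res$dw_simulated),
                   group = rep(c("no diet", "digital biohacking"),
                               each = nrow(res)))
  })
  df <- dplyr::bind_rows(df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dw, fill = .data$group)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.6, bins = 15) +
    ggplot2::facet_wrap(~participant) +
    ggplot2::labs(x = "two-week weight change (kg)", y = "periods",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of weight change against the energy-balance difference
#'
#' Plots per-period weight change against the cumulative difference between
#' the actual and biohacked diet's energy balance, with the fitted
#' regression line.
#'
#' @param outcomes Data frame with `delta_eb` and `dw` columns (for
#'   simulation output, rename `dw_actual` accordingly).
#' @return A ggplot object.
#' @export
plot_dw_vs_deb <- function(outcomes) {
  ggplot2::ggplot(outcomes, ggplot2::aes(x = .data$delta_eb, y = .data$dw)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linewidth = 0.6) +
    ggplot2::labs(x = expression(Delta * EB ~ "(kcal over period)"),
                  y = expression(Delta * w ~ "(kg)")) +
    ggplot2::theme_minimal()
}
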