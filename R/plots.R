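# ggplot2 diagnostics for each result type.

#' @method autoplot kinetic_fit
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  # the fit stores no raw data; draw the implied decay curve over ~2 half-lives
  t_end <- tryCatch(2 * half_life(object$order, max(object$k, 1e-12), object$c0),
                    error = function(e) 1, warning = function(w) 1)
  if (!is.finite(t_end)) t_end <- 1
  tt <- seq(0, t_end, length.out = 200)
  df <- tibble::tibble(time_min = tt,
                       concentration = forward_concentration(object$order, object$k, object$c0, tt))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$concentration)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = "Concentration",
                  title = sprintf("Order %.1f decay, k = %.4g", object$order, object$k))
}

#' @method autoplot arrhenius_fit
#' @export
autoplot.arrhenius_fit <- function(object, ...) {
  # the regression line in (1/T, ln k) space
  df <- tibble::tibble(inv_t = seq(1 / celsius_to_kelvin(80), 1 / celsius_to_kelvin(40),
                                   length.out = 50))
  df$ln_k <- object$ln_a - object$ea * 1000 / .gas_constant * df$inv_t
  ggplot2::ggplot(df, ggplot2::aes(x = .data$inv_t, y = .data$ln_k)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "1/T (1/K)", y = "ln k",
                  title = sprintf("Arrhenius: Ea = %.2f kJ/mol", object$ea))
}

#' Plot observed series against fitted decay curves
#'
#' Observed concentrations (points) and, per temperature, the decay curve at
#' the rate constant fitted at the selected order (lines).
#'
#' @param data Canonical long table.
#' @param fits Output of [fit_kinetics()].
#' @param selection Output of [select_orders()]; recomputed if omitted.
#' @return A ggplot object faceted by compound.
#' @export
plot_kinetics <- function(data, fits, selection = NULL) {
  data <- validate_series_table(data)
  if (is.null(selection)) selection <- select_orders(fits)
  best <- fits |>
    dplyr::inner_join(selection[, c("compound", "best_order")], by = "compound") |>
    dplyr::filter(.data$order == .data$best_order)
  curves <- best |>
    dplyr::group_by(.data$compound, .data$temperature_C) |>
    dplyr::group_modify(function(g, key) {
      grp <- data[data$compound == key$compound & data$temperature_C == key$temperature_C, ]
      tt <- seq(0, max(grp$time_min), length.out = 100)
      tibble::tibble(time_min = tt,
                     concentration = forward_concentration(g$order, g$k, g$c0, tt))
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(data, ggplot2::aes(x = .data$time_min, y = .data$concentration,
                                     colour = factor(.data$temperature_C))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves) +
    ggplot2::facet_wrap(ggplot2::vars(.data$compound), scales = "free_y") +
    ggplot2::labs(x = "Drying time (min)", y = "Concentration (µg/g d.b.)",
                  colour = "T (°C)")
}

#' Predicted-versus-observed validation scatter
#'
#' @param model A `generalized_model`.
#' @param observed Canonical long table for the model's compound.
#' @return A ggplot object with the identity line.
#' @export
plot_validation <- function(model, observed) {
  observed <- validate_series_table(observed)
  pts <- observed |>
    dplyr::group_by(.data$compound, .data$temperature_C) |>
    dplyr::group_modify(function(series, key) {
      agg <- .aggregate_series(series)
      c0 <- agg$concentration[agg$time_min == 0]
      tibble::tibble(observed = agg$concentration,
                     predicted = predict_content(model, key$temperature_C, agg$time_min, c0 = c0))
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$observed, y = .data$predicted,
                                    colour = factor(.data$temperature_C))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Observed concentration", y = "Predicted concentration",
                  colour = "T (°C)")
}
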