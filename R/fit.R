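#' Fit one reaction order to one concentration-time series
#'
#' Linearizes the series with [transform_concentration()] and fits ordinary
#' least squares of the transformed value against time. The rate constant is
#' the absolute slope; goodness of fit is the coefficient of determination on
#' the transformed scale. Replicates are averaged at each time point before
#' transforming. `with_intercept = FALSE` forces the zero-intercept integrated
#' form `y = k t`; the default intercept form matches how slope/intercept
#' pairs feed the temperature-generalized prediction surfaces.
#'
#' @param series Data frame with columns `time_min` and `concentration`
#'   (optionally `replicate`) for one compound at one temperature.
#' @param order Reaction order, one of [kinetic_orders()].
#' @param with_intercept Logical; fit an intercept on the transformed scale.
#' @return A `kinetic_fit` object: fields `order`, `k` (nonnegative rate
#'   constant), `slope` (signed), `intercept`, `r_squared`, `n_points`, `c0`.
#' @examples
#' s <- data.frame(time_min = c(0, 100, 200, 400),
#'                 concentration = forward_concentration(1, 0.01, 100, c(0, 100, 200, 400)))
#' fit_order(s, order = 1)$k
#' @export
fit_order <- function(series, order, with_intercept = TRUE) {
  .check_order(order)
  agg <- .check_series(.aggregate_series(series))
  c0 <- agg$concentration[agg$time_min == 0]
  y <- transform_concentration(order, c0, agg$concentration)
  t <- agg$time_min
  fit <- if (with_intercept) lm(y ~ t) else lm(y ~ t + 0)
  slope <- unname(coef(fit)[["t"]])
  intercept <- if (with_intercept) unname(coef(fit)[["(Intercept)"]]) else 0
  structure(
    list(
      order = order,
      k = abs(slope),
      slope = slope,
      intercept = intercept,
      r_squared = .r_squared(y, stats::fitted(fit)),
      n_points = nrow(agg),
      c0 = c0,
      with_intercept = with_intercept
    ),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> order %.1f: k = %.4g, intercept = %.4g, R^2 = %.4f (n = %d)\n",
              x$order, x$k, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Fit all candidate orders and select the best by R-squared
#'
#' Fits every candidate integrated rate law to the series and selects the
#' order with the highest coefficient of determination on its transformed
#' scale. Orders whose R-squared values differ by less than `tie_tol` are
#' treated as tied and the lower (more parsimonious) order wins.
#'
#' @inheritParams fit_order
#' @param candidate_orders Orders to try; defaults to all of [kinetic_orders()].
#' @param tie_tol R-squared difference below which two orders tie.
#' @return An `order_selection` object: `fits` (one `kinetic_fit` per
#'   candidate, named by order) and `best_order`.
#' @export
select_order <- function(series, candidate_orders = kinetic_orders(),
                         with_intercept = TRUE, tie_tol = 1e-6) {
  fits <- lapply(candidate_orders, function(n) fit_order(series, n, with_intercept))
  names(fits) <- as.character(candidate_orders)
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  best_r2 <- max(r2)
  # lowest order within tie_tol of the maximum
  best_order <- min(candidate_orders[r2 >= best_r2 - tie_tol])
  structure(
    list(fits = fits, best_order = best_order),
    class = "order_selection"
  )
}

#' @export
print.order_selection <- function(x, ...) {
  r2 <- vapply(x$fits, function(f) f$r_squared, numeric(1))
  cat("<order_selection>\n")
  cat("  R^2:", paste(sprintf("%s-order %.4f", names(x$fits), r2), collapse = ", "), "\n")
  cat("  best order:", x$best_order, "\n")
  invisible(x)
}

#' @rdname fit_kinetics
#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    order = x$order, k = x$k, slope = x$slope, intercept = x$intercept,
    r_squared = x$r_squared, n_points = x$n_points, c0 = x$c0
  )
}

#' @rdname fit_kinetics
#' @method tidy order_selection
#' @export
tidy.order_selection <- function(x, ...) {
  purrr::map_dfr(x$fits, tidy) |>
    dplyr::mutate(best = .data$order == x$best_order)
}

#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_points = x$n_points)
}

#' Fit candidate rate laws across a concentration-time table
#'
#' Tibble-first front end to [fit_order()]: fits every candidate order to
#' every compound x temperature series in a canonical long table and returns
#' one row per fit, ready for order selection, Arrhenius regression and the
#' Table-style R-squared grid.
#'
#' @param data Long table with columns `compound`, `temperature_C`,
#'   `time_min`, `concentration`, optional `replicate`.
#' @param orders Candidate reaction orders.
#' @param with_intercept Logical; intercept on the transformed scale.
#' @param x A fitted object, for the `tidy()`/`glance()` methods.
#' @param ... Unused.
#' @return A tibble with columns `compound`, `temperature_C`, `order`, `k`,
#'   `slope`, `intercept`, `r_squared`, `n_points`, `c0`.
#' @export
fit_kinetics <- function(data, orders = kinetic_orders(), with_intercept = TRUE) {
  data <- validate_series_table(data)
  data |>
    dplyr::group_by(.data$compound, .data$temperature_C) |>
    dplyr::group_modify(function(series, key) {
      purrr::map_dfr(orders, function(n) tidy(fit_order(series, n, with_intercept)))
    }) |>
    dplyr::ungroup()
}

#' Select the best reaction order per compound
#'
#' Aggregates the per-series R-squared values of [fit_kinetics()] by compound
#' (mean across temperatures) and picks the order with the highest mean
#' R-squared; ties within `tie_tol` go to the lower order. One order per
#' compound is how degradation studies report their kinetic model choice.
#'
#' @param fits Output of [fit_kinetics()].
#' @param tie_tol R-squared difference treated as a tie.
#' @return A tibble with one row per compound: `compound`, `best_order`,
#'   `mean_r_squared`.
#' @export
select_orders <- function(fits, tie_tol = 1e-6) {
  fits |>
    dplyr::group_by(.data$compound, .data$order) |>
    dplyr::summarise(mean_r_squared = mean(.data$r_squared), .groups = "drop_last") |>
    dplyr::summarise(
      best_order = min(.data$order[.data$mean_r_squared >= max(.data$mean_r_squared) - tie_tol]),
      mean_r_squared = max(.data$mean_r_squared),
      .groups = "drop"
    )
}

#' R-squared grid across orders and temperatures
#'
#' Reshapes [fit_kinetics()] output into the wide compound x temperature by
#' order layout in which degradation studies tabulate goodness of fit.
#'
#' @param fits Output of [fit_kinetics()].
#' @return A wide tibble, one column per candidate order.
#' @export
r_squared_grid <- function(fits) {
  fits |>
    dplyr::select("compound", "temperature_C", "order", "r_squared") |>
    tidyr::pivot_wider(
      names_from = "order", values_from = "r_squared",
      names_glue = "order_{order}"
    )
}
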