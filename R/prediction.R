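# Temperature-generalized prediction: per-temperature linearized fits give a
# slope a(T) and intercept b(T); each coefficient is modelled as a simple
# function of drying temperature (in degrees Celsius), yielding a surface
#   S(T, t) = a(T) * t + b(T)
# on the transformed concentration scale, invertible back to concentration at
# any (T, t) inside the calibrated temperature range.

.coef_bases <- c("constant", "linear", "quadratic", "log")
.basis_nparams <- c(constant = 1L, linear = 2L, quadratic = 3L, log = 2L)

.basis_design <- function(basis, temp_c) {
  n <- length(temp_c)
  switch(basis,
    constant  = matrix(1, n, 1),
    linear    = cbind(temp_c, rep(1, n)),
    quadratic = cbind(temp_c^2, temp_c, rep(1, n)),
    log       = cbind(log(temp_c), rep(1, n)),
    abort(paste0("Unknown basis `", basis, "`."))
  )
}

#' Fit one coefficient-vs-temperature basis
#'
#' Least-squares fit of a per-temperature coefficient (slope or intercept of
#' the linearized kinetic fits) as a function of temperature in degrees
#' Celsius. Bases: `constant`, `linear` (`a1*T + a0`), `quadratic`
#' (`a2*T^2 + a1*T + a0`), `log` (`a1*ln(T) + a0`). Coefficients are stored
#' highest-power first.
#'
#' @param temperatures Degrees Celsius.
#' @param values Coefficient values at those temperatures (signed, as fitted).
#' @param basis One of `"constant"`, `"linear"`, `"quadratic"`, `"log"`.
#' @return A `coefficient_model` list: `basis`, `coefficients`, `r_squared`.
#' @export
fit_coefficient_basis <- function(temperatures, values, basis) {
  basis <- match.arg(basis, .coef_bases)
  p <- .basis_nparams[[basis]]
  if (length(unique(temperatures)) < p) {
    abort(
      paste0("Basis `", basis, "` needs at least ", p,
             " distinct temperatures; got ", length(unique(temperatures)), "."),
      class = "anthokinetics_underdetermined_model_error"
    )
  }
  X <- .basis_design(basis, temperatures)
  beta <- qr.solve(X, values)
  fitted <- drop(X %*% beta)
  structure(
    list(basis = basis, coefficients = unname(beta),
         r_squared = .r_squared(values, fitted)),
    class = "coefficient_model"
  )
}

#' Evaluate a coefficient model at given temperatures
#'
#' @param model A `coefficient_model`.
#' @param temperatures Degrees Celsius.
#' @return Numeric vector of coefficient values.
#' @export
evaluate_coefficient <- function(model, temperatures) {
  drop(.basis_design(model$basis, temperatures) %*% model$coefficients)
}

# Best basis by R^2 with a parsimony rule: among bases whose R^2 is within
# `parsimony_tol` of the maximum, the one with fewest parameters wins (with 3
# temperatures a quadratic interpolates exactly, so raw R^2 alone would always
# pick it).
.select_coefficient_model <- function(temperatures, values, bases, parsimony_tol = 0.01) {
  fits <- list()
  for (b in bases) {
    fit <- tryCatch(fit_coefficient_basis(temperatures, values, b),
                    anthokinetics_underdetermined_model_error = function(e) NULL)
    if (!is.null(fit)) fits[[b]] <- fit
  }
  if (length(fits) == 0) {
    abort("No candidate basis is identifiable with the available temperatures.",
          class = "anthokinetics_underdetermined_model_error")
  }
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  eligible <- names(fits)[r2 >= max(r2) - parsimony_tol]
  winner <- eligible[which.min(.basis_nparams[eligible])]
  fits[[winner]]
}

#' Build a temperature-generalized kinetic prediction model
#'
#' Takes the per-temperature linearized fits of one compound at one reaction
#' order and models the slope `a(T)` and intercept `b(T)` as functions of
#' temperature, each basis selected by R-squared with a parsimony rule
#' (a simpler basis wins unless its R-squared trails by more than
#' `parsimony_tol`).
#'
#' @param fits Tidy fit table (as from [fit_kinetics()]) for one compound,
#'   with columns `temperature_C`, `order`, `slope`, `intercept`, `c0`; all
#'   rows must share one order.
#' @param bases Candidate bases for both coefficient models.
#' @param parsimony_tol R-squared slack within which fewer parameters win.
#' @param direction `+1` if the stored surface uses the canonical transform
#'   orientation (`y = k t`, slopes positive for decay), `-1` for the opposite
#'   sign convention. Inversion back to concentrations respects it either way.
#' @return A `generalized_model`: `order`, `slope_model`, `intercept_model`
#'   (both `coefficient_model`s), `temperature_range`, `c0_reference`,
#'   `direction`.
#' @export
fit_coefficient_models <- function(fits, bases = .coef_bases,
                                   parsimony_tol = 0.01, direction = 1) {
  stopifnot(direction %in% c(-1, 1))
  order <- unique(fits$order)
  if (length(order) != 1) {
    abort("All per-temperature fits must share one reaction order.",
          class = "anthokinetics_validation_error")
  }
  temps <- fits$temperature_C
  structure(
    list(
      order = order,
      slope_model = .select_coefficient_model(temps, fits$slope, bases, parsimony_tol),
      intercept_model = .select_coefficient_model(temps, fits$intercept, bases, parsimony_tol),
      temperature_range = range(temps),
      c0_reference = mean(fits$c0),
      direction = direction
    ),
    class = "generalized_model"
  )
}

#' Assemble a generalized model directly from printed surface coefficients
#'
#' Constructs a `generalized_model` from known coefficient functions (for
#' example, published prediction-equation coefficients) rather than from data.
#'
#' @param order Reaction order of the underlying transform.
#' @param slope_basis,intercept_basis Basis names.
#' @param slope_coefficients,intercept_coefficients Numeric vectors, highest
#'   power first.
#' @param temperature_range Length-2 numeric, degrees Celsius.
#' @param c0_reference Reference initial concentration.
#' @param direction Surface sign convention; see [fit_coefficient_models()].
#' @return A `generalized_model`.
#' @export
generalized_model <- function(order, slope_basis, slope_coefficients,
                              intercept_basis, intercept_coefficients,
                              temperature_range, c0_reference, direction = 1) {
  .check_order(order)
  cm <- function(basis, coefs) {
    basis <- match.arg(basis, .coef_bases)
    stopifnot(length(coefs) == .basis_nparams[[basis]])
    structure(list(basis = basis, coefficients = as.numeric(coefs),
                   r_squared = NA_real_),
              class = "coefficient_model")
  }
  structure(
    list(
      order = order,
      slope_model = cm(slope_basis, slope_coefficients),
      intercept_model = cm(intercept_basis, intercept_coefficients),
      temperature_range = sort(as.numeric(temperature_range)),
      c0_reference = c0_reference,
      direction = direction
    ),
    class = "generalized_model"
  )
}

#' @export
print.generalized_model <- function(x, ...) {
  fmt <- function(m) paste0(m$basis, " [", paste(signif(m$coefficients, 6), collapse = ", "), "]")
  cat(sprintf("<generalized_model> order %.1f\n", x$order))
  cat("  slope a(T):     ", fmt(x$slope_model), "\n")
  cat("  intercept b(T): ", fmt(x$intercept_model), "\n")
  cat(sprintf("  valid: %g-%g degC, C0_ref = %.4g, direction = %+d\n",
              x$temperature_range[1], x$temperature_range[2],
              x$c0_reference, x$direction))
  invisible(x)
}

#' @method tidy generalized_model
#' @export
tidy.generalized_model <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    basis = c(x$slope_model$basis, x$intercept_model$basis),
    coefficients = list(x$slope_model$coefficients, x$intercept_model$coefficients),
    r_squared = c(x$slope_model$r_squared, x$intercept_model$r_squared)
  )
}

.check_extrapolation <- function(model, temperature) {
  lo <- model$temperature_range[1]
  hi <- model$temperature_range[2]
  if (any(temperature < lo | temperature > hi)) {
    warn(sprintf("Temperature outside the calibrated range [%g, %g] degC: extrapolating.",
                 lo, hi))
  }
}

#' Evaluate the prediction surface on the transformed scale
#'
#' Returns `a(T) * t + b(T)` in the model's stored sign convention.
#' Temperatures outside the calibrated range trigger an extrapolation
#' warning, not an error.
#'
#' @param model A `generalized_model`.
#' @param temperature Degrees Celsius.
#' @param time Minutes, nonnegative.
#' @return Transformed-scale surface value(s).
#' @export
evaluate_surface <- function(model, temperature, time) {
  stopifnot(all(time >= 0))
  .check_extrapolation(model, temperature)
  a <- evaluate_coefficient(model$slope_model, temperature)
  b <- evaluate_coefficient(model$intercept_model, temperature)
  a * time + b
}

#' Predict concentration at arbitrary temperature and time
#'
#' Evaluates the generalized surface and inverts the reaction order's
#' transform around the initial concentration `c0`. Surface values implying
#' no decay return `c0`; values outside the invertible range raise a
#' prediction-domain error naming the offending `(T, t)`.
#'
#' @inheritParams evaluate_surface
#' @param c0 Initial concentration; defaults to the model's reference.
#' @return Predicted concentration(s).
#' @export
predict_content <- function(model, temperature, time, c0 = model$c0_reference) {
  stopifnot(c0 > 0)
  s <- evaluate_surface(model, temperature, time)
  y <- pmax(model$direction * s, 0)
  # orders below 1 hit C = 0 at a finite transform value; beyond it the
  # surface is not invertible
  bad <- switch(as.character(model$order),
                "0"   = y >= c0,
                "0.5" = y >= 2 * sqrt(c0),
                rep(FALSE, length(y)))
  if (any(bad)) {
    i <- which(bad)[1]
    abort(
      sprintf("Prediction outside the invertible range at (T = %g degC, t = %g min).",
              rep(temperature, length.out = length(y))[i],
              rep(time, length.out = length(y))[i]),
      class = "anthokinetics_prediction_domain_error"
    )
  }
  invert_transform(model$order, c0, y)
}

#' Validate model predictions against observed series
#'
#' Pooled coefficient of determination of predicted versus observed
#' concentration across all observations of all series: each series supplies
#' its own time-zero concentration as `c0`, predictions are made at its
#' (temperature, time) points, and R-squared is `1 - SSE/SST` over the pooled
#' observations.
#'
#' @param model A `generalized_model`.
#' @param observed Long table in the canonical format (`compound`,
#'   `temperature_C`, `time_min`, `concentration`).
#' @return A tibble with `r_squared`, `n_observations`, `n_series`.
#' @export
validate_predictions <- function(model, observed) {
  observed <- validate_series_table(observed)
  if (nrow(observed) == 0) {
    abort("No observations supplied.", class = "anthokinetics_insufficient_data_error")
  }
  pooled <- observed |>
    dplyr::group_by(.data$compound, .data$temperature_C) |>
    dplyr::group_modify(function(series, key) {
      agg <- .check_series(.aggregate_series(series))
      c0 <- agg$concentration[agg$time_min == 0]
      tibble::tibble(
        time_min = agg$time_min,
        observed = agg$concentration,
        predicted = predict_content(model, key$temperature_C, agg$time_min, c0 = c0)
      )
    }) |>
    dplyr::ungroup()
  tibble::tibble(
    r_squared = .r_squared(pooled$observed, pooled$predicted),
    n_observations = nrow(pooled),
    n_series = nrow(dplyr::distinct(observed[, c("compound", "temperature_C")]))
  )
}

#' Serialize a generalized model to a human-readable YAML document
#'
#' Coefficients are written at full double precision so a written-then-read
#' model predicts bit-for-bit identically.
#'
#' @param model A `generalized_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_generalized_model <- function(model, path) {
  num <- function(x) sprintf("%.17g", x)
  doc <- list(
    order = num(model$order),
    direction = as.integer(model$direction),
    temperature_range = lapply(model$temperature_range, num),
    c0_reference = num(model$c0_reference),
    slope_model = list(basis = model$slope_model$basis,
                       coefficients = lapply(model$slope_model$coefficients, num)),
    intercept_model = list(basis = model$intercept_model$basis,
                           coefficients = lapply(model$intercept_model$coefficients, num))
  )
  writeLines(yaml::as.yaml(doc), path)
  invisible(path)
}

#' Read a serialized generalized model
#'
#' @param path Path written by [write_generalized_model()].
#' @return A `generalized_model`.
#' @export
read_generalized_model <- function(path) {
  doc <- yaml::read_yaml(path)
  generalized_model(
    order = as.numeric(doc$order),
    slope_basis = doc$slope_model$basis,
    slope_coefficients = as.numeric(unlist(doc$slope_model$coefficients)),
    intercept_basis = doc$intercept_model$basis,
    intercept_coefficients = as.numeric(unlist(doc$intercept_model$coefficients)),
    temperature_range = as.numeric(unlist(doc$temperature_range)),
    c0_reference = as.numeric(doc$c0_reference),
    direction = as.numeric(doc$direction)
  )
}
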