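# Temperature dependence of fitted rate constants: Q10 ratios, Arrhenius
# activation energy from ln k vs 1/T, and Eyring activation thermodynamics.

#' Q10 temperature coefficient from a pair of rate constants
#'
#' The factor by which the degradation rate increases for a 10 degree C rise,
#' taken as the ratio of the fitted rate constants at temperatures 10 degrees
#' apart: `k(T + 10) / k(T)`.
#'
#' @param k_low Rate constant at the lower temperature; positive.
#' @param k_high Rate constant at the higher temperature (10 degrees above).
#' @return Unitless Q10 factor.
#' @examples
#' q10(0.0094, 0.0177)  # ~1.88
#' @export
q10 <- function(k_low, k_high) {
  if (any(k_low <= 0)) {
    abort("`k_low` must be positive.", class = "anthokinetics_domain_error")
  }
  k_high / k_low
}

#' Q10 implied by an Arrhenius law
#'
#' The closed-form Q10 at temperature `temp_c` for activation energy `ea`:
#' `exp(Ea/R * 10 / (T_K * (T_K + 10)))`. Complements [q10()], which uses the
#' fitted rate-constant ratio directly.
#'
#' @param ea Activation energy in kJ/mol.
#' @param temp_c Lower temperature of the 10-degree interval, in Celsius.
#' @return Unitless Q10 factor.
#' @export
q10_arrhenius <- function(ea, temp_c) {
  tk <- celsius_to_kelvin(temp_c)
  exp(ea * 1000 / .gas_constant * 10 / (tk * (tk + 10)))
}

#' Arrhenius regression of rate constants on temperature
#'
#' Ordinary least squares of `ln k` on `1/T` (T in Kelvin). The activation
#' energy is `-slope * R`, reported in kJ/mol; the intercept is `ln A` with A
#' the pre-exponential factor.
#'
#' @param temperatures Temperatures in degrees Celsius (at least 2 distinct).
#' @param ks Positive rate constants, one per temperature.
#' @return An `arrhenius_fit` object with fields `ea` (kJ/mol), `ln_a`,
#'   `r_squared` (`NA` with fewer than 3 temperatures) and `n_temperatures`.
#' @examples
#' arrhenius_fit(c(50, 60, 70), c(0.0094, 0.0177, 0.0229))$ea  # ~41.21
#' @export
arrhenius_fit <- function(temperatures, ks) {
  stopifnot(length(temperatures) == length(ks))
  if (any(ks <= 0)) {
    abort("All rate constants must be positive for the log-linear Arrhenius fit.",
          class = "anthokinetics_domain_error")
  }
  if (length(unique(temperatures)) < 2) {
    abort("At least 2 distinct temperatures are required.",
          class = "anthokinetics_degenerate_design_error")
  }
  inv_t <- 1 / celsius_to_kelvin(temperatures)
  lnk <- log(ks)
  fit <- lm(lnk ~ inv_t)
  r2 <- if (length(unique(temperatures)) >= 3) .r_squared(lnk, stats::fitted(fit)) else NA_real_
  structure(
    list(
      ea = -unname(coef(fit)[["inv_t"]]) * .gas_constant / 1000,
      ln_a = unname(coef(fit)[["(Intercept)"]]),
      r_squared = r2,
      n_temperatures = length(unique(temperatures))
    ),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> Ea = %.2f kJ/mol, ln A = %.3f (n = %d temperatures",
              x$ea, x$ln_a, x$n_temperatures))
  if (!is.na(x$r_squared)) cat(sprintf(", R^2 = %.4f", x$r_squared))
  cat(")\n")
  invisible(x)
}

#' @method tidy arrhenius_fit
#' @export
tidy.arrhenius_fit <- function(x, ...) {
  tibble::tibble(ea = x$ea, ln_a = x$ln_a, r_squared = x$r_squared,
                 n_temperatures = x$n_temperatures)
}

#' @method glance arrhenius_fit
#' @export
glance.arrhenius_fit <- function(x, ...) tidy(x)

#' Eyring activation thermodynamics from a rate constant
#'
#' Transition-state parameters at one temperature:
#' `deltaH = Ea - R T`, `deltaG = -R T ln(k h / (kB T))`, and
#' `deltaS = (deltaH - deltaG) / T`, with h the Planck constant and kB the
#' Boltzmann constant.
#'
#' Reported activation free energies in food-degradation studies conventionally
#' insert the rate constant in per-minute units directly into the Eyring
#' expression alongside h in J s; `k_units = "per-min"` (the default) follows
#' that convention. `k_units = "per-sec"` first converts k to per-second,
#' which shifts deltaG by `R T ln(60)`.
#'
#' @param ea Activation energy, kJ/mol.
#' @param k Rate constant in per-minute units; positive.
#' @param temp_c Temperature in degrees Celsius.
#' @param k_units `"per-min"` (convention of the reported tables) or
#'   `"per-sec"` (dimensionally consistent).
#' @return A tibble with columns `delta_h`, `delta_g` (kJ/mol) and `delta_s`
#'   (kJ/(mol K)); the identity `delta_s == (delta_h - delta_g)/T_K` holds by
#'   construction.
#' @examples
#' eyring(41.21, k = 0.0094, temp_c = 50)  # delta_g ~ 91.90 kJ/mol
#' @export
eyring <- function(ea, k, temp_c, k_units = c("per-min", "per-sec")) {
  k_units <- match.arg(k_units)
  if (any(k <= 0)) {
    abort("`k` must be positive.", class = "anthokinetics_domain_error")
  }
  tk <- celsius_to_kelvin(temp_c)
  k_num <- if (k_units == "per-sec") k / 60 else k
  delta_h <- ea - .gas_constant * tk / 1000
  delta_g <- -.gas_constant * tk * log(k_num * .planck / (.boltzmann * tk)) / 1000
  tibble::tibble(
    delta_h = delta_h,
    delta_g = delta_g,
    delta_s = (delta_h - delta_g) / tk
  )
}

#' Kinetic and thermodynamic summary table
#'
#' Builds the per compound x temperature report conventional in degradation
#' studies: rate constant, half-life, activation energy, Eyring parameters and
#' Q10 to the next-higher tabulated temperature. Uses the fits at each
#' compound's selected order.
#'
#' @param fits Output of [fit_kinetics()].
#' @param selection Output of [select_orders()]; computed from `fits` if
#'   omitted.
#' @param k_units Passed to [eyring()].
#' @return A tibble with one row per compound x temperature: `k`, `t_half`,
#'   `ea`, `delta_h`, `delta_g`, `delta_s`, `q10_to_next`.
#' @export
summarize_thermo <- function(fits, selection = NULL,
                             k_units = c("per-min", "per-sec")) {
  k_units <- match.arg(k_units)
  if (is.null(selection)) selection <- select_orders(fits)
  best <- fits |>
    dplyr::inner_join(selection[, c("compound", "best_order")], by = "compound") |>
    dplyr::filter(.data$order == .data$best_order) |>
    dplyr::arrange(.data$compound, .data$temperature_C)

  best |>
    dplyr::group_by(.data$compound) |>
    dplyr::group_modify(function(g, key) {
      ea <- if (length(unique(g$temperature_C)) >= 2) {
        arrhenius_fit(g$temperature_C, g$k)$ea
      } else {
        NA_real_
      }
      ey <- eyring(ea, g$k, g$temperature_C, k_units = k_units)
      tibble::tibble(
        temperature_C = g$temperature_C,
        order = g$order,
        k = g$k,
        t_half = vapply(seq_len(nrow(g)), function(i) {
          half_life(g$order[i], g$k[i], g$c0[i])
        }, numeric(1)),
        ea = ea,
        delta_h = ey$delta_h,
        delta_g = ey$delta_g,
        delta_s = ey$delta_s,
        q10_to_next = c(g$k[-1] / g$k[-nrow(g)], NA_real_)
      )
    }) |>
    dplyr::ungroup()
}
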