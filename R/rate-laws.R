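# Integrated rate laws for dC/dt = -k C^n, n in {0, 0.5, 1, 1.5, 2}.
#
# Each order has a linearizing transform y(C0, Ct) with y = k t for a decaying
# series, oriented so that y >= 0 and the fitted rate constant is nonnegative:
#   n = 0   : y = C0 - Ct
#   n = 0.5 : y = 2 (sqrt(C0) - sqrt(Ct))
#   n = 1   : y = ln(C0 / Ct)
#   n = 1.5 : y = 2 (1/sqrt(Ct) - 1/sqrt(C0))
#   n = 2   : y = 1/Ct - 1/C0

#' Linearizing transform of an integrated rate law
#'
#' Maps a pair of concentrations (initial `c0`, current `ct`) to the
#' transformed-scale value `y` that grows linearly in time under `order`-th
#' order decay, i.e. `y = k * t` for a noiseless trajectory. `y` is zero when
#' `ct == c0` and positive when `ct < c0`.
#'
#' @param order Reaction order, one of `kinetic_orders()`.
#' @param c0 Initial concentration (time zero), must be positive.
#' @param ct Concentration at the evaluation time; positive. Vectorized.
#' @return Transformed-scale value(s), same length as `ct`.
#' @examples
#' transform_concentration(2, c0 = 2, ct = 1)      # 0.5
#' transform_concentration(1.5, c0 = 4, ct = 1)    # 1
#' @export
transform_concentration <- function(order, c0, ct) {
  .check_order(order)
  if (any(c0 <= 0) || any(ct <= 0)) {
    abort(
      paste0("Concentrations must be positive for the order-", order,
             " transform (fractional and logarithmic forms are undefined at C <= 0)."),
      class = "anthokinetics_domain_error"
    )
  }
  switch(
    as.character(order),
    "0"   = c0 - ct,
    "0.5" = 2 * (sqrt(c0) - sqrt(ct)),
    "1"   = log(c0 / ct),
    "1.5" = 2 * (1 / sqrt(ct) - 1 / sqrt(c0)),
    "2"   = 1 / ct - 1 / c0
  )
}

#' Invert a linearizing transform back to a concentration
#'
#' Given a transformed-scale value `y` (so that `y = k t` on a noiseless
#' trajectory), returns the concentration `Ct` with
#' `transform_concentration(order, c0, Ct) == y`. Values of `y` below zero
#' (no decay implied) return `c0`; values beyond the invertible range of the
#' order (e.g. implying `1/Ct <= 0`) raise a prediction-domain error.
#'
#' @inheritParams transform_concentration
#' @param y Transformed-scale value(s).
#' @return Concentration(s).
#' @export
invert_transform <- function(order, c0, y) {
  .check_order(order)
  stopifnot(c0 > 0)
  y <- pmax(y, 0)
  ct <- switch(
    as.character(order),
    "0"   = c0 - y,
    "0.5" = (sqrt(c0) - y / 2)^2 * sign(sqrt(c0) - y / 2),
    "1"   = c0 * exp(-y),
    "1.5" = 1 / (y / 2 + 1 / sqrt(c0))^2,
    "2"   = 1 / (y + 1 / c0)
  )
  if (any(ct <= 0)) {
    abort(
      paste0("Transformed value implies a nonpositive concentration under order ",
             order, "; outside the invertible range."),
      class = "anthokinetics_prediction_domain_error"
    )
  }
  ct
}

#' Closed-form forward simulation of n-th order decay
#'
#' Evaluates the integrated rate law `C(t)` for `dC/dt = -k C^n` with
#' `C(0) = c0`. Orders below 1 reach zero at a finite extinction time and are
#' clipped there; orders 1 and above decay asymptotically.
#'
#' @inheritParams transform_concentration
#' @param k Rate constant (per minute, scaled by concentration^(1-order));
#'   nonnegative.
#' @param t Time(s) in minutes, nonnegative. Vectorized.
#' @return Concentration(s) at `t`.
#' @examples
#' forward_concentration(1, k = 0.01, c0 = 100, t = c(0, 69.3))
#' forward_concentration(0, k = 1, c0 = 10, t = 2)   # 8
#' @export
forward_concentration <- function(order, k, c0, t) {
  .check_order(order)
  stopifnot(k >= 0, c0 > 0, all(t >= 0))
  switch(
    as.character(order),
    "0"   = pmax(c0 - k * t, 0),
    "0.5" = pmax(sqrt(c0) - k * t / 2, 0)^2,
    "1"   = c0 * exp(-k * t),
    "1.5" = 1 / (1 / sqrt(c0) + k * t / 2)^2,
    "2"   = 1 / (1 / c0 + k * t)
  )
}

#' Half-life of n-th order decay
#'
#' Time for the concentration to fall to half its initial value. For order 1
#' this is `ln(2)/k`; for any other order
#' `(2^(n-1) - 1) / ((n - 1) k c0^(n-1))`, which reduces to the familiar
#' `1/(k C0)` at order 2 and `2(sqrt(2)-1)/(k sqrt(C0))` at order 1.5.
#'
#' @inheritParams forward_concentration
#' @return Half-life in minutes; `Inf` (with a warning) when `k == 0`.
#' @examples
#' half_life(1, k = log(2))        # 1 minute
#' half_life(2, k = 1, c0 = 1)     # 1 minute
#' @export
half_life <- function(order, k, c0 = NULL) {
  .check_order(order)
  if (k == 0) {
    warn("Rate constant is zero: half-life is infinite.")
    return(Inf)
  }
  stopifnot(k > 0)
  if (order == 1) return(log(2) / k)
  if (is.null(c0) || c0 <= 0) {
    abort("`c0` must be a positive concentration for non-first-order half-lives.",
          class = "anthokinetics_domain_error")
  }
  n <- order
  (2^(n - 1) - 1) / ((n - 1) * k * c0^(n - 1))
}
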