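test_that("linearizing transforms match their analytic forms", {
  expect_equal(transform_concentration(2, c0 = 100, ct = 100), 0)
  expect_equal(transform_concentration(1.5, c0 = 4, ct = 1), 1)
  expect_equal(transform_concentration(2, c0 = 2, ct = 1), 0.5)
  expect_equal(transform_concentration(0, c0 = 10, ct = 7), 3)
  expect_equal(transform_concentration(0.5, c0 = 9, ct = 4), 2)
  expect_equal(transform_concentration(1, c0 = exp(2), ct = 1), 2)
  # identity at ct = c0, positive for decay, for every order
  for (n in kinetic_orders()) {
    expect_equal(transform_concentration(n, 5, 5), 0)
    expect_gt(transform_concentration(n, 5, 3), 0)
  }
})

test_that("fractional and log transforms refuse nonpositive concentrations", {
  expect_error(transform_concentration(1.5, c0 = 1, ct = 0),
               class = "anthokinetics_domain_error")
  expect_error(transform_concentration(1, c0 = -1, ct = 1),
               class = "anthokinetics_domain_error")
  expect_error(transform_concentration(3, c0 = 1, ct = 1),
               class = "anthokinetics_order_error")
})

test_that("forward simulation honours initial value, decay and clipping", {
  expect_equal(forward_concentration(1, k = 0.01, c0 = 100, t = 0), 100)
  expect_equal(forward_concentration(0, k = 1, c0 = 10, t = 2), 8)
  # orders below 1 extinguish in finite time and clip at zero
  expect_equal(forward_concentration(0, k = 1, c0 = 10, t = 50), 0)
  expect_equal(forward_concentration(0.5, k = 2, c0 = 4, t = 100), 0)
  # every order: C(0) = c0 and nonincreasing in both t and k
  tt <- seq(0, 300, by = 25)
  for (n in kinetic_orders()) {
    cc <- forward_concentration(n, 0.01, 50, tt)
    expect_equal(cc[1], 50)
    expect_true(all(diff(cc) <= 1e-12))
    c_slow <- forward_concentration(n, 0.005, 50, 100)
    c_fast <- forward_concentration(n, 0.02, 50, 100)
    expect_lte(c_fast, c_slow)
  }
})

test_that("forward simulation halves the initial content at the closed-form half-life", {
  # initial content back-solved from a tabulated 2-order half-life
  c0 <- 1 / (0.0094 * 74.53)
  expect_equal(forward_concentration(2, 0.0094, c0, 74.53), c0 / 2, tolerance = 1e-9)
})

test_that("transform and forward simulation are exact inverses (y = k t)", {
  grid <- expand.grid(order = kinetic_orders(), k = c(5e-4, 0.01, 0.2),
                      c0 = c(0.5, 40, 390.4))
  for (i in seq_len(nrow(grid))) {
    n <- grid$order[i]; k <- grid$k[i]; c0 <- grid$c0[i]
    # stay strictly before extinction for orders < 1
    t_max <- if (n < 1) 0.9 * c0^(1 - n) / ((1 - n) * k) else 500
    tt <- seq(0, t_max, length.out = 7)
    ct <- forward_concentration(n, k, c0, tt)
    expect_equal(transform_concentration(n, c0, ct), k * tt, tolerance = 1e-9)
  }
})

test_that("invert_transform undoes transform_concentration and flags impossible values", {
  for (n in kinetic_orders()) {
    ct <- c(39, 17.2, 4.4)
    y <- transform_concentration(n, 40, ct)
    expect_equal(invert_transform(n, 40, y), ct, tolerance = 1e-12)
  }
  # negative transformed values imply no decay: clamp to c0
  expect_equal(invert_transform(2, 10, -0.3), 10)
  # beyond extinction for orders < 1 the transform is not invertible
  expect_error(invert_transform(0, c0 = 10, y = 10),
               class = "anthokinetics_prediction_domain_error")
  expect_error(invert_transform(0.5, c0 = 4, y = 4),
               class = "anthokinetics_prediction_domain_error")
})

test_that("closed forms agree with independent numerical ODE integration", {
  skip_if_not_installed("deSolve")
  grid <- expand.grid(order = kinetic_orders(), k = c(0.002, 0.05),
                      c0 = c(2, 120))
  for (i in seq_len(nrow(grid))) {
    n <- grid$order[i]; k <- grid$k[i]; c0 <- grid$c0[i]
    t_max <- if (n < 1) 0.9 * c0^(1 - n) / ((1 - n) * k) else 200
    tt <- seq(0, t_max, length.out = 9)
    ode <- deSolve::lsoda(
      y = c(C = c0), times = tt,
      func = function(t, y, p) list(-p$k * max(y[1], 0)^p$n),
      parms = list(k = k, n = n), rtol = 1e-10, atol = 1e-12
    )
    expect_equal(forward_concentration(n, k, c0, tt), unname(ode[, "C"]),
                 tolerance = 1e-6)
  }
})

test_that("half-life closed forms are exact and match a bisection oracle", {
  expect_equal(half_life(1, k = log(2)), 1)
  expect_equal(half_life(2, k = 1, c0 = 1), 1)
  # 1.5-order: initial content back-solved from a tabulated half-life
  c0 <- (2 * (sqrt(2) - 1) / (0.0003 * 141.43))^2
  expect_equal(half_life(1.5, k = 0.0003, c0 = c0), 141.43, tolerance = 1e-9)
  # numeric root of C(t) = c0/2 agrees with the closed form for every order
  for (n in kinetic_orders()) {
    k <- 0.013; c0 <- 77
    th <- half_life(n, k, c0)
    root <- uniroot(function(t) forward_concentration(n, k, c0, t) - c0 / 2,
                    interval = c(0, 10 * th), tol = 1e-12)$root
    expect_equal(th, root, tolerance = 1e-8)
  }
  # forward simulation halves c0 at t_half
  for (n in kinetic_orders()) {
    th <- half_life(n, 0.004, 25)
    expect_equal(forward_concentration(n, 0.004, 25, th), 12.5, tolerance = 1e-9)
  }
  expect_warning(out <- half_life(1, k = 0), "infinite")
  expect_identical(out, Inf)
})
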