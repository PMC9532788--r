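# Published prediction-surface coefficients used as fixtures throughout:
# 1.5-order surface: a(T) = -6e-6 T^2 + 6e-4 T - 0.0153 (quadratic),
#                    b(T) = 0.0628 ln T - 0.2741 (log), stored with the
#                    opposite-sign transform orientation (direction = -1);
# 2-order surface:   a(T) = -7e-4 T + 0.0238 (linear),
#                    b(T) = -0.0049 T^2 + 0.5696 T - 16.34 (quadratic).
surface_15 <- generalized_model(
  order = 1.5, slope_basis = "quadratic", slope_coefficients = c(-6e-6, 6e-4, -0.0153),
  intercept_basis = "log", intercept_coefficients = c(0.0628, -0.2741),
  temperature_range = c(50, 70), c0_reference = 390.4, direction = -1
)
surface_2 <- generalized_model(
  order = 2, slope_basis = "linear", slope_coefficients = c(-7e-4, 0.0238),
  intercept_basis = "quadratic", intercept_coefficients = c(-0.0049, 0.5696, -16.34),
  temperature_range = c(50, 70), c0_reference = 1.4274, direction = -1
)

test_that("coefficient bases are recovered exactly from exact data", {
  temps <- c(50, 60, 70)
  lin <- fit_coefficient_basis(temps, -7e-4 * temps + 0.0238, "linear")
  expect_equal(lin$coefficients, c(-7e-4, 0.0238), tolerance = 1e-12)
  expect_equal(lin$r_squared, 1, tolerance = 1e-12)
  lg <- fit_coefficient_basis(temps, 0.0628 * log(temps) - 0.2741, "log")
  expect_equal(lg$coefficients, c(0.0628, -0.2741), tolerance = 1e-10)
  expect_error(fit_coefficient_basis(c(50, 60), rep(1, 2), "quadratic"),
               class = "anthokinetics_underdetermined_model_error")
})

test_that("basis selection maximizes R-squared with a parsimony rule", {
  temps <- c(50, 60, 70)
  # strongly curved coefficient: only the quadratic basis fits
  fits <- tibble::tibble(
    temperature_C = temps, order = 2,
    slope = (temps - 60)^2 / 100, intercept = 0.1 * temps, c0 = 10
  )
  m <- fit_coefficient_models(fits)
  expect_equal(m$slope_model$basis, "quadratic")
  expect_equal(m$slope_model$r_squared, 1, tolerance = 1e-12)
  # exactly linear coefficient: linear ties the interpolating quadratic and
  # wins on parsimony
  expect_equal(m$intercept_model$basis, "linear")
  expect_error(
    fit_coefficient_models(dplyr::mutate(fits, order = c(2, 2, 1.5))),
    class = "anthokinetics_validation_error"
  )
})

test_that("the prediction surface evaluates a(T) t + b(T) in the stored orientation", {
  # slope arithmetic on the published 1.5-order coefficients at 50 degC
  expect_equal(evaluate_coefficient(surface_15$slope_model, 50), -3e-4, tolerance = 1e-9)
  # and on the 2-order coefficients at 60 degC
  expect_equal(evaluate_coefficient(surface_2$slope_model, 60), -0.0182, tolerance = 1e-9)
  # at t = 0 the surface is b(T)
  expect_equal(evaluate_surface(surface_15, 60, 0),
               0.0628 * log(60) - 0.2741, tolerance = 1e-12)
  expect_equal(evaluate_surface(surface_2, 60, 100),
               -0.0182 * 100 + (-0.0049 * 3600 + 0.5696 * 60 - 16.34), tolerance = 1e-9)
  expect_warning(evaluate_surface(surface_15, 90, 10), "extrapolat")
})

test_that("predict_content inverts the transform and respects its domain", {
  # order 2 with unit c0: transformed value 1 means 1/Ct = 2, so Ct = 0.5
  m <- generalized_model(2, "constant", 1, "constant", 0,
                         temperature_range = c(50, 70), c0_reference = 1)
  expect_equal(predict_content(m, 60, 1), 0.5)
  # zero surface at t = 0 returns c0
  expect_equal(predict_content(m, 60, 0), 1)
  expect_equal(predict_content(m, 60, 0, c0 = 7), 7)
  # a surface implying growth is clamped to no decay
  m_up <- generalized_model(2, "constant", -0.5, "constant", 0,
                            temperature_range = c(50, 70), c0_reference = 1)
  expect_equal(predict_content(m_up, 60, 4), 1)
  # order-0 surface beyond extinction names the offending point
  m0 <- generalized_model(0, "constant", 1, "constant", 0,
                          temperature_range = c(50, 70), c0_reference = 5)
  expect_error(predict_content(m0, 60, 6),
               class = "anthokinetics_prediction_domain_error")
})

test_that("a model built from exact per-temperature fits reproduces training data", {
  # rate constants exactly linear in temperature so the linear basis is exact
  ks <- c("50" = 0.004, "60" = 0.006, "70" = 0.008)
  d <- make_table(2, ks, c0 = 8, time_grids = drying_grids)
  fits <- fit_kinetics(d) |> dplyr::filter(order == 2)
  m <- fit_coefficient_models(fits)
  expect_equal(m$slope_model$r_squared, 1, tolerance = 1e-9)
  v <- validate_predictions(m, d)
  expect_equal(v$r_squared, 1, tolerance = 1e-9)
  expect_equal(v$n_series, 3L)
  # inversion: predicted content round-trips through the transform
  y <- transform_concentration(2, 8, predict_content(m, 60, 240, c0 = 8))
  expect_equal(invert_transform(2, 8, y), predict_content(m, 60, 240, c0 = 8),
               tolerance = 1e-12)
})

test_that("predicted concentration is nonincreasing in time under a decay slope", {
  tt <- seq(0, 400, by = 40)
  for (m in list(surface_15, surface_2)) {
    p <- predict_content(m, 60, tt)
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("the generalized model tracks the generator within tolerance at 5% noise", {
  cfg <- red_cabbage_config(noise_scale = 0.05, seed = 7)
  d <- generate_dataset(cfg)
  fits <- fit_kinetics(d) |> dplyr::filter(compound == "C3dG5G-like", order == 1.5)
  m <- fit_coefficient_models(fits)
  pred <- predict_content(m, 60, 240, c0 = 390.4)
  truth <- forward_concentration(1.5, 0.0006, 390.4, 240)
  expect_lt(abs(pred - truth) / truth, 0.15)
})

test_that("degenerate validation sets are handled as defined", {
  expect_error(validate_predictions(surface_2, tibble::tibble(
    compound = character(), temperature_C = numeric(),
    time_min = numeric(), concentration = numeric()
  )), class = "anthokinetics_insufficient_data_error")
  # constant observations with decaying predictions: zero total variance and
  # nonzero residuals gives the -Inf sentinel, which never beats a real fit
  const <- tibble::tibble(compound = "x", temperature_C = 60,
                          time_min = c(0, 100, 200), concentration = 1.4274)
  v <- validate_predictions(surface_2, const)
  expect_lte(v$r_squared, 0)
})

test_that("model serialization round-trips bit-for-bit", {
  path <- withr::local_tempfile(fileext = ".yml")
  write_generalized_model(surface_15, path)
  back <- read_generalized_model(path)
  expect_identical(back$slope_model$coefficients, surface_15$slope_model$coefficients)
  expect_identical(back$intercept_model$coefficients, surface_15$intercept_model$coefficients)
  expect_identical(back$direction, surface_15$direction)
  tt <- c(0, 60, 240)
  expect_identical(predict_content(back, 60, tt), predict_content(surface_15, 60, tt))
})
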