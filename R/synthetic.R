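# Seeded generator for concentration-time datasets with the structure the
# pipeline assumes: per-compound reaction order, Arrhenius (or tabulated)
# rate constants across drying temperatures, replicate observations with
# multiplicative or additive noise.

#' Define a degrading-compound archetype
#'
#' A compound archetype carries everything needed to simulate its decay: the
#' true reaction order, initial concentration, and the rate constant as a
#' function of temperature — either through an Arrhenius law anchored at a
#' reference temperature, or as exact per-temperature values (useful when
#' tabulated rate constants are not perfectly Arrhenius-consistent).
#'
#' @param compound Label.
#' @param order True reaction order, one of [kinetic_orders()].
#' @param c0 Initial concentration, micrograms per gram dry basis.
#' @param ea Activation energy, kJ/mol (used when no exact k is tabulated for
#'   a temperature).
#' @param k_ref Rate constant at `t_ref_C`.
#' @param t_ref_C Reference temperature, degrees Celsius.
#' @param k_by_temperature Optional named numeric vector of exact rate
#'   constants, names = temperature in degrees Celsius.
#' @return An `archetype` list.
#' @export
archetype <- function(compound, order, c0, ea = NULL, k_ref = NULL,
                      t_ref_C = NULL, k_by_temperature = NULL) {
  .check_order(order)
  stopifnot(c0 > 0)
  if (is.null(k_by_temperature) && (is.null(ea) || is.null(k_ref) || is.null(t_ref_C))) {
    abort("Provide either `k_by_temperature` or the Arrhenius triple (`ea`, `k_ref`, `t_ref_C`).")
  }
  structure(
    list(compound = compound, order = order, c0 = c0, ea = ea,
         k_ref = k_ref, t_ref_C = t_ref_C, k_by_temperature = k_by_temperature),
    class = "archetype"
  )
}

#' Rate constant of an archetype at a temperature
#'
#' Uses the tabulated exact value when one exists for `temp_c` (exact-k mode),
#' otherwise the Arrhenius law through (`ea`, `k_ref`, `t_ref_C`).
#'
#' @param arch An [archetype()].
#' @param temp_c Temperature, degrees Celsius.
#' @param exact_k Prefer tabulated per-temperature values when available.
#' @return Rate constant.
#' @export
archetype_k <- function(arch, temp_c, exact_k = TRUE) {
  key <- as.character(temp_c)
  if (exact_k && !is.null(arch$k_by_temperature) && key %in% names(arch$k_by_temperature)) {
    return(unname(arch$k_by_temperature[[key]]))
  }
  if (is.null(arch$ea)) {
    abort(sprintf("No tabulated k at %g degC and no Arrhenius parameters for `%s`.",
                  temp_c, arch$compound))
  }
  tk <- celsius_to_kelvin(temp_c)
  tref <- celsius_to_kelvin(arch$t_ref_C)
  arch$k_ref * exp(-arch$ea * 1000 / .gas_constant * (1 / tk - 1 / tref))
}

#' Assemble a generator configuration
#'
#' @param archetypes List of [archetype()] objects.
#' @param temperatures Drying temperatures, degrees Celsius.
#' @param time_grids Named list (names = temperature) of sampling times in
#'   minutes; each grid must include 0.
#' @param noise_model `"multiplicative_lognormal"` (noise scale = coefficient
#'   of variation) or `"additive_gaussian"` (noise scale = absolute standard
#'   deviation).
#' @param noise_scale Nonnegative noise scale.
#' @param replicates Replicate observations per time point (>= 1).
#' @param seed Integer; fully determines generator output.
#' @param exact_k Use tabulated per-temperature rate constants when present.
#' @param concentration_floor Lowest admissible concentration under additive
#'   noise; draws at or below it are resampled.
#' @return A `generator_config` list.
#' @export
generator_config <- function(archetypes, temperatures, time_grids,
                             noise_model = c("multiplicative_lognormal", "additive_gaussian"),
                             noise_scale = 0.05, replicates = 3L, seed = 1L,
                             exact_k = TRUE, concentration_floor = 1e-6) {
  noise_model <- match.arg(noise_model)
  stopifnot(noise_scale >= 0, replicates >= 1)
  missing_grids <- setdiff(as.character(temperatures), names(time_grids))
  if (length(missing_grids) > 0) {
    abort(paste0("No time grid for temperature(s): ", paste(missing_grids, collapse = ", ")))
  }
  for (tg in time_grids) {
    if (min(tg) != 0) abort("Every time grid must include a time-zero point.")
  }
  structure(
    list(archetypes = archetypes, temperatures = as.numeric(temperatures),
         time_grids = time_grids, noise_model = noise_model,
         noise_scale = noise_scale, replicates = as.integer(replicates),
         seed = as.integer(seed), exact_k = exact_k,
         concentration_floor = concentration_floor),
    class = "generator_config"
  )
}

#' Red cabbage drying configuration
#'
#' Default configuration emulating anthocyanin degradation in red cabbage
#' under air-impingement jet drying at 50, 60 and 70 degrees C: a 1.5-order
#' degrader patterned on cyanidin-3-diglucoside-5-glucoside (k = 0.0003,
#' 0.0006, 0.0020 per min; Ea 87.19 kJ/mol; C0 390.4 ug/g d.b., about a
#' quarter of fresh total anthocyanin content 1546.18 ug/g d.b.) and a
#' 2-order degrader patterned on the cyanidin aglycone (k = 0.0094, 0.0177,
#' 0.0229 per min; Ea 41.21 kJ/mol; C0 derived from the 50 degC half-life via
#' `1/(k * t_half)`). Sampling grids follow the drying schedules at each
#' temperature; three replicates with 5% multiplicative noise.
#'
#' @param noise_scale Coefficient of variation of the multiplicative noise.
#' @param replicates Replicates per time point.
#' @param seed Integer seed.
#' @param exact_k Use the tabulated rate constants (default) rather than the
#'   Arrhenius interpolation, which does not reproduce them exactly.
#' @return A `generator_config`.
#' @export
red_cabbage_config <- function(noise_scale = 0.05, replicates = 3L, seed = 1L,
                               exact_k = TRUE) {
  generator_config(
    archetypes = list(
      archetype(
        compound = "C3dG5G-like", order = 1.5, c0 = 390.4,
        ea = 87.19, k_ref = 0.0006, t_ref_C = 60,
        k_by_temperature = c("50" = 0.0003, "60" = 0.0006, "70" = 0.0020)
      ),
      archetype(
        compound = "cyanidin-like", order = 2, c0 = 1 / (0.0094 * 74.53),
        ea = 41.21, k_ref = 0.0177, t_ref_C = 60,
        k_by_temperature = c("50" = 0.0094, "60" = 0.0177, "70" = 0.0229)
      )
    ),
    temperatures = c(50, 60, 70),
    time_grids = list(
      "50" = c(0, 150, 300, 480, 720),
      "60" = c(0, 120, 240, 420, 630),
      "70" = c(0, 60, 150, 240, 450)
    ),
    noise_model = "multiplicative_lognormal",
    noise_scale = noise_scale,
    replicates = replicates,
    seed = seed,
    exact_k = exact_k
  )
}

# Run `expr` under `seed` without disturbing the caller's RNG stream.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic concentration-time dataset
#'
#' For each archetype x temperature x replicate, evaluates the closed-form
#' decay curve at the temperature's sampling grid and perturbs it with the
#' configured noise model. Output is fully determined by the configuration's
#' seed (or the `seed` argument, which overrides it).
#'
#' @param config A [generator_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return A tibble in the canonical long format: `compound`,
#'   `temperature_C`, `replicate`, `time_min`, `concentration`, plus the
#'   noise-free `concentration_true`.
#' @examples
#' head(generate_dataset(red_cabbage_config(noise_scale = 0, replicates = 1)))
#' @export
generate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  seed <- seed %||% config$seed
  .with_seed(seed, {
    grid <- tidyr::expand_grid(
      arch = config$archetypes,
      temperature_C = config$temperatures,
      replicate = seq_len(config$replicates)
    )
    out <- purrr::pmap_dfr(grid, function(arch, temperature_C, replicate) {
      times <- config$time_grids[[as.character(temperature_C)]]
      k <- archetype_k(arch, temperature_C, exact_k = config$exact_k)
      true <- forward_concentration(arch$order, k, arch$c0, times)
      obs <- .apply_noise(true, config)
      tibble::tibble(
        compound = arch$compound,
        temperature_C = temperature_C,
        replicate = replicate,
        time_min = times,
        concentration = obs,
        concentration_true = true
      )
    })
    out
  })
}

.apply_noise <- function(true, config) {
  n <- length(true)
  if (config$noise_scale == 0) return(true)
  if (config$noise_model == "multiplicative_lognormal") {
    # lognormal with unit mean and coefficient of variation = noise_scale;
    # keeps concentrations strictly positive
    sdlog <- sqrt(log(1 + config$noise_scale^2))
    true * rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    obs <- true + rnorm(n, 0, config$noise_scale)
    resampled <- 0L
    for (i in which(obs <= config$concentration_floor)) {
      for (try in 1:20) {
        obs[i] <- true[i] + rnorm(1, 0, config$noise_scale)
        if (obs[i] > config$concentration_floor) break
      }
      if (obs[i] <= config$concentration_floor) obs[i] <- config$concentration_floor
      resampled <- resampled + 1L
    }
    if (resampled > 0) {
      rlang::inform(sprintf("Additive noise drove %d draw(s) to the floor; resampled.", resampled))
    }
    obs
  }
}

#' Write a generator configuration as a YAML document
#'
#' @param config A `generator_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(config, path) {
  doc <- list(
    temperatures = config$temperatures,
    time_grids = config$time_grids,
    noise_model = config$noise_model,
    noise_scale = config$noise_scale,
    replicates = config$replicates,
    seed = config$seed,
    exact_k = config$exact_k,
    concentration_floor = config$concentration_floor,
    archetypes = lapply(config$archetypes, function(a) {
      list(compound = a$compound, order = a$order, c0 = a$c0,
           ea = a$ea, k_ref = a$k_ref, t_ref_C = a$t_ref_C,
           k_by_temperature = as.list(a$k_by_temperature))
    })
  )
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

#' Read a generator configuration from YAML
#'
#' @param path Path written by [write_generator_config()].
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  doc <- yaml::read_yaml(path)
  generator_config(
    archetypes = lapply(doc$archetypes, function(a) {
      kbt <- if (length(a$k_by_temperature)) unlist(a$k_by_temperature) else NULL
      archetype(a$compound, a$order, a$c0, ea = a$ea, k_ref = a$k_ref,
                t_ref_C = a$t_ref_C, k_by_temperature = kbt)
    }),
    temperatures = unlist(doc$temperatures),
    time_grids = lapply(doc$time_grids, unlist),
    noise_model = doc$noise_model,
    noise_scale = doc$noise_scale,
    replicates = doc$replicates,
    seed = doc$seed,
    exact_k = doc$exact_k,
    concentration_floor = doc$concentration_floor
  )
}
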