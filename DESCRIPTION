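Package: anthokinetics
Title: Degradation Kinetics and Thermodynamics of Anthocyanins During Drying
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-order degradation kinetics for thermally labile pigments,
    built around the integrated rate laws of orders 0, 0.5, 1, 1.5 and 2.
    Fits linearized rate equations to concentration-time series, selects the
    reaction order by coefficient of determination, and derives half-lives,
    Q10 temperature coefficients, Arrhenius activation energies and Eyring
    activation thermodynamics (enthalpy, Gibbs free energy, entropy) from the
    fitted rate constants. Builds temperature-generalized prediction
    equations whose slope and intercept are modelled as functions of drying
    temperature, and validates predicted against observed concentrations.
    Includes a seeded synthetic-data generator emulating anthocyanin
    degradation in red cabbage under air-impingement jet drying, so the full
    pipeline is testable without raw measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
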