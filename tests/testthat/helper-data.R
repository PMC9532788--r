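# Small builders used across test files.

# Noiseless series table for one compound at one temperature.
make_series <- function(order, k, c0, times, compound = "x", temp_c = 60) {
  tibble::tibble(
    compound = compound,
    temperature_C = temp_c,
    time_min = times,
    concentration = forward_concentration(order, k, c0, times)
  )
}

# Noiseless multi-temperature table for one compound with tabulated ks.
make_table <- function(order, ks, c0, time_grids, compound = "x") {
  purrr::imap_dfr(ks, function(k, temp) {
    make_series(order, k, c0, time_grids[[temp]], compound, as.numeric(temp))
  })
}

# The drying-schedule sampling grids used throughout.
drying_grids <- list(
  "50" = c(0, 150, 300, 480, 720),
  "60" = c(0, 120, 240, 420, 630),
  "70" = c(0, 60, 150, 240, 450)
)
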