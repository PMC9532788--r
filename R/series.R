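# Canonical tabular form: one row per observation, columns
#   compound (chr), temperature_C (dbl), time_min (dbl), concentration (dbl),
#   replicate (optional). One compound x temperature group is a degradation
# series, the unit of kinetic fitting.

.series_cols <- c("compound", "temperature_C", "time_min", "concentration")

#' Validate a concentration-time table
#'
#' Checks the canonical long format: required columns present, numeric where
#' expected, concentrations strictly positive, times nonnegative.
#'
#' @param data A data frame with columns `compound`, `temperature_C`,
#'   `time_min`, `concentration` and optionally `replicate`.
#' @return The data, as a tibble, invisibly unchanged apart from class.
#' @export
validate_series_table <- function(data) {
  missing_cols <- setdiff(.series_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "anthokinetics_schema_error"
    )
  }
  for (col in c("temperature_C", "time_min", "concentration")) {
    if (!is.numeric(data[[col]])) {
      abort(paste0("Column `", col, "` must be numeric."),
            class = "anthokinetics_schema_error")
    }
  }
  bad <- which(!is.finite(data$concentration) | data$concentration <= 0)
  if (length(bad) > 0) {
    abort(
      paste0("Nonpositive or missing concentration at row(s): ",
             paste(head(bad, 5), collapse = ", "),
             if (length(bad) > 5) " ..." else ""),
      class = "anthokinetics_validation_error"
    )
  }
  if (any(data$time_min < 0)) {
    abort("Negative times are not allowed.", class = "anthokinetics_validation_error")
  }
  tibble::as_tibble(data)
}

# Collapse replicates by mean concentration at each time point and order by
# time; one fitted curve per temperature, as is conventional for drying series.
.aggregate_series <- function(data) {
  data |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(concentration = mean(.data$concentration), .groups = "drop") |>
    dplyr::arrange(.data$time_min)
}

# Validate one aggregated series for fitting: >= 3 distinct times, a
# time-zero observation (defines C0), positive concentrations.
.check_series <- function(series) {
  if (nrow(series) < 3) {
    abort("At least 3 distinct time points are required to fit a rate law.",
          class = "anthokinetics_insufficient_data_error")
  }
  if (stats::var(series$time_min) == 0) {
    abort("All observations share one time point; the design is degenerate.",
          class = "anthokinetics_degenerate_design_error")
  }
  if (min(series$time_min) != 0) {
    abort("A time-zero observation is required to define C0.",
          class = "anthokinetics_validation_error")
  }
  if (any(series$concentration <= 0)) {
    abort("All concentrations must be positive.",
          class = "anthokinetics_validation_error")
  }
  series
}

# Coefficient of determination 1 - SSE/SST about the mean of `obs`.
# Degenerate SST (zero variance): 1 if the residuals vanish, else -Inf so the
# fit can never win a model-selection comparison.
.r_squared <- function(obs, fitted) {
  sse <- sum((obs - fitted)^2)
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) {
    if (sse < 1e-12) 1 else -Inf
  } else {
    1 - sse / sst
  }
}
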