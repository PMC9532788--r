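# End-to-end analysis: order selection -> thermodynamic summaries ->
# Arrhenius regression -> temperature-generalized prediction model ->
# predicted-vs-observed validation, assembled into a reproducible report.

#' Run the full degradation-kinetics pipeline
#'
#' For each compound in the table: fits all candidate integrated rate laws at
#' every temperature, selects the reaction order, summarizes rate constants,
#' half-lives, Q10 and Eyring thermodynamics, regresses the Arrhenius
#' activation energy, builds the temperature-generalized prediction model,
#' and validates its predictions against the input observations. With a
#' single temperature the Arrhenius/Q10/prediction stages are omitted and
#' noted in the report.
#'
#' @param data Canonical long table (or a file path readable by
#'   [read_series_table()]).
#' @param orders Candidate reaction orders.
#' @param with_intercept Intercept on the transformed scale for the
#'   per-series fits feeding the prediction surfaces.
#' @param k_units Eyring rate-constant unit convention, see [eyring()].
#' @param seed Seed recorded in the report provenance (the pipeline itself is
#'   deterministic).
#' @return An `analysis_report` with elements `r2_grid`, `selection`,
#'   `thermo`, `arrhenius`, `models`, `validation`, `notes`, `provenance`.
#' @export
run_pipeline <- function(data, orders = kinetic_orders(), with_intercept = TRUE,
                         k_units = c("per-min", "per-sec"), seed = NULL) {
  k_units <- match.arg(k_units)
  input_digest <- NULL
  if (is.character(data) && length(data) == 1) {
    input_digest <- sprintf("%s (%d bytes)", basename(data), file.info(data)$size)
    data <- read_series_table(data)
  }
  data <- validate_series_table(data)
  if (nrow(data) == 0) {
    abort("Empty input: nothing to analyse.", class = "anthokinetics_schema_error")
  }

  fits <- fit_kinetics(data, orders = orders, with_intercept = with_intercept)
  selection <- select_orders(fits)
  thermo <- summarize_thermo(fits, selection, k_units = k_units)

  notes <- character()
  arrhenius <- fits |>
    dplyr::inner_join(selection[, c("compound", "best_order")], by = "compound") |>
    dplyr::filter(.data$order == .data$best_order) |>
    dplyr::group_by(.data$compound) |>
    dplyr::group_modify(function(g, key) {
      if (length(unique(g$temperature_C)) < 2) {
        return(tibble::tibble(ea = NA_real_, ln_a = NA_real_,
                              r_squared = NA_real_, n_temperatures = 1L))
      }
      tidy(arrhenius_fit(g$temperature_C, g$k))
    }) |>
    dplyr::ungroup()
  if (any(arrhenius$n_temperatures < 2)) {
    notes <- c(notes, "Single-temperature compound(s): Arrhenius and Q10 omitted.")
  }

  models <- list()
  validation <- tibble::tibble(compound = character(), r_squared = numeric(),
                               n_observations = integer(), n_series = integer())
  for (cmp in selection$compound) {
    cmp_fits <- fits |>
      dplyr::filter(.data$compound == cmp,
                    .data$order == selection$best_order[selection$compound == cmp])
    if (length(unique(cmp_fits$temperature_C)) < 2) {
      notes <- c(notes, sprintf("`%s`: too few temperatures for a generalized model.", cmp))
      next
    }
    model <- fit_coefficient_models(cmp_fits)
    models[[cmp]] <- model
    v <- validate_predictions(model, data[data$compound == cmp, ])
    validation <- dplyr::bind_rows(validation, dplyr::bind_cols(tibble::tibble(compound = cmp), v))
  }

  structure(
    list(
      r2_grid = r_squared_grid(fits),
      fits = fits,
      selection = selection,
      thermo = thermo,
      arrhenius = arrhenius,
      models = models,
      validation = validation,
      notes = notes,
      provenance = list(
        input = input_digest %||% "in-memory table",
        n_rows = nrow(data),
        orders = orders,
        with_intercept = with_intercept,
        k_units = k_units,
        seed = seed,
        tool_version = as.character(packageVersion("anthokinetics"))
      )
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Degradation kinetics report ==\n\n")
  cat("R^2 by candidate order:\n")
  print(x$r2_grid, n = Inf)
  cat("\nSelected orders:\n")
  print(x$selection, n = Inf)
  cat("\nKinetic and thermodynamic parameters:\n")
  print(x$thermo, n = Inf)
  cat("\nArrhenius:\n")
  print(x$arrhenius, n = Inf)
  if (nrow(x$validation) > 0) {
    cat("\nPrediction validation (predicted vs observed):\n")
    print(x$validation, n = Inf)
  }
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits a machine-readable JSON document (`report.json`), flat CSV tables of
#' the R-squared grid and thermodynamic summary, and the serialized
#' generalized model per compound. JSON output is deterministic for identical
#' inputs, configuration and seed.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(
      r2_grid = report$r2_grid,
      selection = report$selection,
      thermo = report$thermo,
      arrhenius = report$arrhenius,
      validation = report$validation,
      notes = report$notes,
      provenance = report$provenance
    ),
    file.path(dir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  readr::write_csv(report$r2_grid, file.path(dir, "r2_grid.csv"))
  readr::write_csv(report$thermo, file.path(dir, "thermo.csv"))
  for (cmp in names(report$models)) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", cmp)
    write_generalized_model(report$models[[cmp]], file.path(dir, paste0("model_", safe, ".yml")))
  }
  invisible(dir)
}
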