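# Delimited-text readers/writers for the canonical long format. Comma is the
# default delimiter; tab is accepted. Temperatures are degrees Celsius by
# declaration of the header: no unit sniffing.

#' Read a concentration-time table
#'
#' Reads a delimited text file with header columns `compound`,
#' `temperature_C`, `time_min`, `concentration` and optionally `replicate`,
#' validates it, and returns the canonical tibble sorted by compound,
#' temperature and time. Malformed numeric cells are reported with their
#' location.
#'
#' @param path File path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return A validated tibble in canonical long format.
#' @export
read_series_table <- function(path, delim = ",") {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "anthokinetics_schema_error")
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  if (nrow(raw) == 0) {
    abort(paste0("No data rows in ", path), class = "anthokinetics_schema_error")
  }
  missing_cols <- setdiff(.series_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s) in ", path, ": ",
                 paste(missing_cols, collapse = ", ")),
          class = "anthokinetics_schema_error")
  }
  for (col in c("temperature_C", "time_min", "concentration")) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(
        sprintf("Nonnumeric value in column `%s` at data row(s) %s of %s.",
                col, paste(head(bad, 5), collapse = ", "), path),
        class = "anthokinetics_parse_error"
      )
    }
    raw[[col]] <- parsed
  }
  out <- validate_series_table(raw) |>
    dplyr::arrange(.data$compound, .data$temperature_C, .data$time_min)
  out
}

#' Write a concentration-time table
#'
#' @param data Canonical long table.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_series_table <- function(data, path, delim = ",") {
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}
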