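#' Read one survey's child records from CSV
#'
#' Reads a UTF-8 CSV with a header row, one row per child, renames columns
#' through an optional column map, and validates the result against the
#' schema via [survey_dataset()] (complete-case rows are dropped and
#' counted). This lets DHS-style exports and synthetic files share one
#' reader.
#'
#' @param path Path to the CSV file.
#' @param schema A [survey_schema()].
#' @param column_map Optional named character vector mapping canonical names
#'   (schema variables, `weight`, `waz`, `underweight`, `survey`) to the
#'   file's column names, e.g. `c(weight = "wt", wealth = "v190")`.
#' @param survey Optional survey label override.
#' @return A `survey_dataset`.
#' @export
read_survey_csv <- function(path, schema, column_map = NULL, survey = NULL) {
  if (!file.exists(path) || file.size(path) == 0) {
    abort(paste0("Cannot read survey CSV: `", path, "` is missing or empty."),
          class = "nd_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0L) {
    abort(paste0("Survey CSV `", path, "` has no data rows."), class = "nd_io_error")
  }
  if (!is.null(column_map)) {
    missing <- setdiff(unname(column_map), names(df))
    if (length(missing) > 0) {
      abort(paste0("Mapped column(s) not in `", path, "`: ",
                   paste0("`", missing, "`", collapse = ", "), "."),
            class = "nd_io_error")
    }
    for (canon in names(column_map)) {
      names(df)[names(df) == column_map[[canon]]] <- canon
    }
  }
  survey_dataset(df, schema, survey = survey)
}

#' Write a survey dataset back to CSV
#'
#' Writing then re-reading with the same schema preserves the records.
#'
#' @param dataset A `survey_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "survey_dataset"))
  readr::write_csv(dataset$data, path, progress = FALSE)
  invisible(path)
}

#' Write a result table to CSV
#'
#' Dispatches on result type: decomposition results are written in the
#' report shape (one row per covariate category with E and C estimates,
#' confidence intervals and percentage shares, plus a totals row); trend
#' tables are written as-is. Full precision is kept; rounding is applied
#' only by the print methods.
#'
#' @param result A `decomposition` or `trend_table` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  UseMethod("write_results")
}

#' @export
write_results.decomposition <- function(result, path) {
  readr::write_csv(decomposition_report(result), path, progress = FALSE)
  invisible(path)
}

#' @export
write_results.trend_table <- function(result, path) {
  readr::write_csv(tibble::as_tibble(result), path, progress = FALSE)
  invisible(path)
}
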