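#' Build a survey dataset of child records
#'
#' Validates one survey's child-level records against a covariate schema and
#' applies complete-case filtering: rows missing the outcome, the sampling
#' weight, or any schema covariate are dropped and counted. The binary
#' underweight outcome is taken from an `underweight` column if present, or
#' derived from a `waz` column as `waz < -2`; when both are present they
#' must agree.
#'
#' @param data A data frame with one row per child: the schema covariates
#'   (category labels), a `weight` column (non-negative sampling weight),
#'   and `underweight` (0/1) and/or `waz` (numeric Z-score). An optional
#'   `survey` column carries the survey label.
#' @param schema A [survey_schema()].
#' @param survey Survey label; defaults to the unique value of the
#'   `survey` column.
#' @return A `survey_dataset`: list with `data` (tibble of validated
#'   records), `survey`, `schema`, and `n_dropped` (complete-case drops).
#' @export
survey_dataset <- function(data, schema, survey = NULL) {
  stopifnot(inherits(schema, "survey_schema"))
  data <- tibble::as_tibble(data)
  vars <- names(schema)

  missing_cols <- setdiff(c(vars, "weight"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste0("`", missing_cols, "`", collapse = ", "), "."),
          class = "nd_io_error")
  }
  has_waz <- "waz" %in% names(data)
  has_uw  <- "underweight" %in% names(data)
  if (!has_waz && !has_uw) {
    abort("Need an outcome column: `underweight` (0/1) or `waz` (Z-score).",
          class = "nd_io_error")
  }
  if (!is.numeric(data$weight)) {
    bad <- which(is.na(suppressWarnings(as.numeric(data$weight))) &
                   !is.na(data$weight))
    abort(paste0("Column `weight` is not numeric (first bad row: ",
                 if (length(bad)) bad[1] else NA, ")."),
          class = "nd_parse_error")
  }

  if (is.null(survey)) {
    if ("survey" %in% names(data)) {
      lab <- unique(as.character(data$survey[!is.na(data$survey)]))
      if (length(lab) != 1L) {
        abort("Column `survey` must hold a single label; pass `survey=` to override.",
              class = "nd_validation_error")
      }
      survey <- lab
    } else {
      abort("No `survey` column found; supply the `survey` label.",
            class = "nd_validation_error")
    }
  }
  survey <- as.character(survey)

  # complete cases over outcome, weight and modeled covariates
  outcome_ok <- if (has_uw) !is.na(data$underweight) else !is.na(data$waz)
  if (has_waz && !has_uw) outcome_ok <- outcome_ok & is.finite(data$waz)
  cov_ok <- !Reduce(`|`, lapply(vars, function(v) is.na(data[[v]])))
  keep <- outcome_ok & !is.na(data$weight) & cov_ok
  n_dropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  if (nrow(data) == 0L) {
    abort("No complete-case records remain.", class = "nd_validation_error")
  }

  if (any(data$weight < 0)) {
    abort("Sampling weights must be non-negative.", class = "nd_validation_error")
  }
  for (v in vars) {
    data[[v]] <- as.character(data[[v]])
    bad <- setdiff(unique(data[[v]]), schema[[v]])
    if (length(bad) > 0) {
      abort(paste0("Unseen categor", if (length(bad) > 1) "ies" else "y",
                   " in `", v, "`: ", paste0("\"", bad, "\"", collapse = ", "),
                   " not in schema."),
            class = "nd_schema_error")
    }
  }

  if (has_waz && has_uw) {
    chk <- is.finite(data$waz)
    derived <- as.integer(data$waz[chk] < -2)
    if (!all(as.integer(data$underweight[chk]) == derived)) {
      abort("`underweight` disagrees with `waz < -2` for some rows.",
            class = "nd_validation_error")
    }
  }
  if (!has_uw) data$underweight <- is_underweight(data$waz)
  uw <- data$underweight
  if (!all(uw %in% c(0, 1))) {
    abort("`underweight` must be 0/1.", class = "nd_validation_error")
  }
  data$underweight <- as.integer(uw)
  data$survey <- survey

  structure(
    list(data = data, survey = survey, schema = schema, n_dropped = n_dropped),
    class = "survey_dataset"
  )
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset> survey ", x$survey, ": ", nrow(x$data), " records (",
      x$n_dropped, " dropped as incomplete), ",
      length(x$schema), " covariates\n", sep = "")
  prev <- 100 * sum(x$data$weight * x$data$underweight) / sum(x$data$weight)
  cat("  weighted underweight prevalence: ", sprintf("%.2f%%", prev), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.survey_dataset <- function(x, ...) x$data
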