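#' Weighted underweight prevalence, overall or by stratum
#'
#' Computes `100 * sum(w * y) / sum(w)` overall or within each category of
#' one stratifying covariate. Schema categories with no (or zero-weight)
#' records are reported as missing, with a message.
#'
#' @param dataset A `survey_dataset`.
#' @param stratifier Optional name of a schema covariate.
#' @return A tibble with columns `variable`, `category`, `n`, `prevalence`
#'   (percent). With `stratifier = NULL` a single row with
#'   `variable = "overall"`.
#' @export
weighted_prevalence <- function(dataset, stratifier = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  d <- dataset$data
  if (is.null(stratifier)) {
    return(tibble::tibble(
      variable = "overall", category = NA_character_, n = nrow(d),
      prevalence = 100 * sum(d$weight * d$underweight) / sum(d$weight)
    ))
  }
  if (!stratifier %in% names(dataset$schema)) {
    abort(paste0("`", stratifier, "` is not a schema covariate."),
          class = "nd_schema_error")
  }
  out <- purrr::map_dfr(dataset$schema[[stratifier]], function(cat) {
    rows <- d[d[[stratifier]] == cat, ]
    wsum <- sum(rows$weight)
    tibble::tibble(
      variable = stratifier, category = cat, n = nrow(rows),
      prevalence = if (nrow(rows) == 0L || wsum <= 0) NA_real_ else
        100 * sum(rows$weight * rows$underweight) / wsum
    )
  })
  if (any(is.na(out$prevalence))) {
    inform(paste0("Empty or zero-weight stratum in `", stratifier, "` (survey ",
                  dataset$survey, "): ",
                  paste(out$category[is.na(out$prevalence)], collapse = ", "),
                  " reported as missing."))
  }
  out
}

#' Phase differences between surveys
#'
#' Adds, for each requested survey pair, a percentage-point difference
#' column computed as later minus earlier (a decline is negative).
#'
#' @param prevalences A data frame with one numeric prevalence column per
#'   survey label (plus any identifier columns such as `variable`,
#'   `category`).
#' @param pairs List of 2-vectors `c(earlier, later)`.
#' @return The input tibble with one extra column per pair, named
#'   `"<later>-<earlier>"`.
#' @examples
#' tb <- tibble::tibble(category = "Tigray",
#'                      `2005` = 30.16, `2011` = 35.63, `2016` = 24.46)
#' phase_differences(tb, list(c("2011", "2016")))
#' @export
phase_differences <- function(prevalences, pairs) {
  prevalences <- tibble::as_tibble(prevalences)
  for (pr in pairs) {
    if (length(pr) != 2L || !all(pr %in% names(prevalences))) {
      abort(paste0("Survey pair (", paste(pr, collapse = ", "),
                   ") not present in the prevalence table."),
            class = "nd_contract_error")
    }
    earlier <- pr[1]; later <- pr[2]
    prevalences[[paste0(later, "-", earlier)]] <-
      prevalences[[later]] - prevalences[[earlier]]
  }
  prevalences
}

#' Stratified prevalence trend table with phase differences
#'
#' Weighted underweight prevalence per subgroup and survey, with
#' percentage-point phase differences (later minus earlier) for each
#' requested survey pair, and an overall row.
#'
#' @param datasets Named list of `survey_dataset`s sharing one schema
#'   (names are ignored; survey labels come from the datasets).
#' @param stratifiers Covariates to stratify by; default all schema
#'   variables.
#' @param pairs List of survey-label pairs `c(earlier, later)`; default all
#'   consecutive pairs plus first-vs-last when more than two surveys.
#' @return A `trend_table` tibble: `variable`, `category`, one prevalence
#'   column per survey, one difference column per pair; the first row is
#'   the overall trend.
#' @export
trend_table <- function(datasets, stratifiers = NULL, pairs = NULL) {
  stopifnot(length(datasets) >= 2L,
            all(vapply(datasets, inherits, logical(1), "survey_dataset")))
  labels <- vapply(datasets, function(d) d$survey, character(1))
  if (anyDuplicated(labels)) {
    abort("Datasets must carry distinct survey labels.",
          class = "nd_validation_error")
  }
  schema <- datasets[[1]]$schema
  stratifiers <- stratifiers %||% names(schema)
  if (is.null(pairs)) {
    pairs <- lapply(seq_len(length(labels) - 1L),
                    function(i) c(labels[i], labels[i + 1L]))
    if (length(labels) > 2L) {
      pairs <- c(pairs, list(c(labels[1], labels[length(labels)])))
    }
  }
  long <- purrr::map_dfr(datasets, function(ds) {
    rows <- dplyr::bind_rows(
      weighted_prevalence(ds),
      purrr::map_dfr(stratifiers, function(v) weighted_prevalence(ds, v))
    )
    rows$survey <- ds$survey
    rows
  })
  wide <- tidyr::pivot_wider(
    dplyr::select(long, "variable", "category", "survey", "prevalence"),
    names_from = "survey", values_from = "prevalence"
  )
  out <- phase_differences(wide, pairs)
  structure(out, class = c("trend_table", class(out)),
            pairs = pairs, surveys = unname(labels))
}

#' Plot the overall prevalence trend
#'
#' @param object A `trend_table`.
#' @param ... Unused.
#' @return A ggplot line chart of overall weighted prevalence by survey.
#' @exportS3Method ggplot2::autoplot
autoplot.trend_table <- function(object, ...) {
  surveys <- attr(object, "surveys")
  overall <- object[object$variable == "overall", surveys, drop = FALSE]
  df <- tibble::tibble(survey = surveys,
                       prevalence = as.numeric(overall[1, ]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$survey, y = .data$prevalence,
                                   group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Survey", y = "Weighted underweight prevalence (%)",
                  title = "Overall underweight trend")
}
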