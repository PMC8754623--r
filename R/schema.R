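#' Define a covariate schema
#'
#' A schema fixes, for each categorical covariate, its ordered category list
#' and its reference (baseline) category. The reference is always the first
#' category; [set_reference()] reorders a variable so a chosen category
#' becomes the baseline. Column order in design matrices follows schema
#' order, then category order, so results are deterministic.
#'
#' @param ... Named character vectors, one per covariate, each listing the
#'   variable's categories with the reference category first. A single named
#'   list may be supplied instead.
#' @return A `survey_schema` object (named list of character vectors).
#' @examples
#' sch <- survey_schema(
#'   wealth = c("Poor", "Middle", "Rich"),
#'   residence = c("Urban", "Rural")
#' )
#' set_reference(sch, "wealth", "Rich")
#' @export
survey_schema <- function(...) {
  vars <- list(...)
  if (length(vars) == 1L && is.list(vars[[1]]) && !is.character(vars[[1]])) {
    vars <- vars[[1]]
  }
  if (length(vars) == 0L) {
    abort("A schema needs at least one covariate.", class = "nd_validation_error")
  }
  nms <- names(vars)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms)) {
    abort("Schema variables must have unique non-empty names.",
          class = "nd_validation_error")
  }
  for (v in nms) {
    lv <- vars[[v]]
    if (!is.character(lv) || length(lv) < 2L || anyDuplicated(lv) || any(is.na(lv))) {
      abort(
        paste0("Schema variable `", v,
               "` must list at least two distinct, non-missing categories."),
        class = "nd_validation_error"
      )
    }
  }
  structure(lapply(vars, as.character), class = "survey_schema")
}

#' @export
print.survey_schema <- function(x, ...) {
  cat("<survey_schema> ", length(x), " covariate(s)\n", sep = "")
  for (v in names(x)) {
    cat("  ", v, ": ", paste(x[[v]], collapse = ", "),
        "  (reference: ", x[[v]][1], ")\n", sep = "")
  }
  invisible(x)
}

#' @rdname survey_schema
#' @param schema A `survey_schema`.
#' @param variable Name of a schema variable.
#' @param reference Category to use as the new baseline (moved first).
#' @export
set_reference <- function(schema, variable, reference) {
  stopifnot(inherits(schema, "survey_schema"))
  if (!variable %in% names(schema)) {
    abort(paste0("Unknown schema variable `", variable, "`."),
          class = "nd_schema_error")
  }
  lv <- schema[[variable]]
  if (!reference %in% lv) {
    abort(paste0("`", reference, "` is not a category of `", variable, "`."),
          class = "nd_schema_error")
  }
  schema[[variable]] <- c(reference, setdiff(lv, reference))
  schema
}

#' Default covariate schema for the bundled demonstration scenario
#'
#' Six child/household covariates with DHS-style categories; the baselines
#' follow common reporting practice for underweight decompositions
#' (education "None", wealth "Poor", residence "Urban", birth size
#' "Below average").
#'
#' @return A `survey_schema`.
#' @export
default_schema <- function() {
  survey_schema(
    women_education  = c("None", "Primary", "Secondary+"),
    wealth           = c("Poor", "Middle", "Rich"),
    residence        = c("Urban", "Rural"),
    child_sex        = c("Female", "Male"),
    birth_size       = c("Below average", "Average+"),
    place_of_delivery = c("Home", "H institution")
  )
}

# number of dummy (non-reference) columns implied by a schema, excl. intercept
schema_n_dummies <- function(schema) {
  sum(vapply(schema, length, integer(1)) - 1L)
}
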