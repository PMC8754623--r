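#' Build a dummy-coded design matrix from a survey dataset
#'
#' Expands the schema covariates to treatment (dummy) coding with the
#' reference category omitted and a leading intercept column. Column order
#' is deterministic: schema order, then category order. The `groups` map
#' records which columns belong to each categorical variable, which the
#' decomposition needs for reference-category normalisation and detailed
#' contributions.
#'
#' @param dataset A `survey_dataset`.
#' @return A `design_matrix`: list with `X` (N x K numeric matrix, first
#'   column the intercept), `y` (binary outcome), `w` (weights), `cols`
#'   (tibble mapping columns to variable/category), `groups` (named list of
#'   column indices per variable) and `survey`.
#' @export
build_design <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  data <- dataset$data
  schema <- dataset$schema
  n <- nrow(data)

  cols <- list(tibble::tibble(column = "(Intercept)",
                              variable = "(Intercept)", category = NA_character_))
  mats <- list(matrix(1, nrow = n, ncol = 1))
  groups <- list()
  k <- 1L
  for (v in names(schema)) {
    lv <- schema[[v]]
    observed <- unique(data[[v]])
    if (length(observed) < 2L) {
      abort(paste0("Covariate `", v, "` has a single observed category (\"",
                   observed, "\"); it cannot enter the model."),
            class = "nd_degenerate_covariate")
    }
    nonref <- lv[-1]
    m <- vapply(nonref, function(cat) as.numeric(data[[v]] == cat),
                numeric(n))
    m <- matrix(m, nrow = n)
    const <- vapply(seq_len(ncol(m)), function(j) {
      all(m[, j] == m[1, j])
    }, logical(1))
    if (any(const)) {
      abort(paste0("Constant dummy column for `", v, "` (category ",
                   paste0("\"", nonref[const], "\"", collapse = ", "),
                   "): level unobserved or ubiquitous."),
            class = "nd_degenerate_covariate")
    }
    colnames(m) <- paste(v, nonref, sep = ".")
    mats[[length(mats) + 1L]] <- m
    cols[[length(cols) + 1L]] <- tibble::tibble(
      column = colnames(m), variable = v, category = nonref)
    groups[[v]] <- k + seq_along(nonref)
    k <- k + length(nonref)
  }
  X <- do.call(cbind, mats)
  colnames(X) <- c("(Intercept)", unlist(lapply(mats[-1], colnames)))

  structure(
    list(X = X, y = data$underweight, w = data$weight,
         cols = dplyr::bind_rows(cols), groups = groups,
         schema = schema, survey = dataset$survey),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> survey ", x$survey, ": ", nrow(x$X), " x ", ncol(x$X),
      " (intercept + ", ncol(x$X) - 1L, " dummies over ",
      length(x$groups), " variables)\n", sep = "")
  invisible(x)
}

# Expand a dummy-coded design to full indicator coding (one column per
# category, reference included), matching the coefficient expansion used by
# reference-category normalisation. Reference indicator = 1 - sum(nonref).
expand_design <- function(design) {
  X <- design$X
  n <- nrow(X)
  mats <- list(matrix(1, n, 1))
  cols <- list(tibble::tibble(column = "(Intercept)",
                              variable = "(Intercept)", category = NA_character_))
  groups <- list()
  k <- 1L
  for (v in names(design$groups)) {
    idx <- design$groups[[v]]
    lv <- design$schema[[v]]
    ref_col <- 1 - rowSums(X[, idx, drop = FALSE])
    m <- cbind(ref_col, X[, idx, drop = FALSE])
    colnames(m) <- paste(v, lv, sep = ".")
    mats[[length(mats) + 1L]] <- m
    cols[[length(cols) + 1L]] <- tibble::tibble(
      column = colnames(m), variable = v, category = lv)
    groups[[v]] <- k + seq_along(lv)
    k <- k + length(lv)
  }
  Xf <- do.call(cbind, mats)
  colnames(Xf) <- c("(Intercept)", unlist(lapply(mats[-1], colnames)))
  list(X = Xf, cols = dplyr::bind_rows(cols), groups = groups)
}
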