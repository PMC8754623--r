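# Linear map T from dummy-coded coefficients (K, intercept first) to
# deviation-coded coefficients on the expanded (all-categories) scale:
# within each variable the reference effect 0 and the dummy effects are
# centred on their unweighted mean over all L categories, and the removed
# means are absorbed into the intercept. X_expanded %*% (T beta) equals
# X %*% beta for every row, so the linear predictor is unchanged.
normalization_matrix <- function(groups, K, expanded_cols) {
  Ke <- nrow(expanded_cols)
  T <- matrix(0, nrow = Ke, ncol = K)
  T[1, 1] <- 1
  row <- 1L
  for (v in names(groups)) {
    idx <- groups[[v]]          # original dummy columns for v
    L <- length(idx) + 1L       # categories incl. reference
    T[1, idx] <- T[1, idx] + 1 / L
    # expanded rows: reference first, then the dummy categories in order
    ref_row <- row + 1L
    T[ref_row, idx] <- -1 / L
    for (j in seq_along(idx)) {
      r <- ref_row + j
      T[r, idx] <- -1 / L
      T[r, idx[j]] <- T[r, idx[j]] + 1
    }
    row <- row + L
  }
  T
}

#' Reference-category (deviation) normalisation of a fitted model
#'
#' Re-expresses each categorical variable's effects in deviation-from-mean
#' form: the within-variable effects (reference = 0) are centred on their
#' unweighted mean across all of the variable's categories, and the removed
#' means are added to the intercept. The linear predictor of every
#' observation is unchanged. Detailed decomposition rows computed from the
#' normalised coefficients do not depend on which category was chosen as
#' the baseline.
#'
#' @param fit A `wlogit`.
#' @param design The `design_matrix` the fit was estimated on (supplies the
#'   variable groups and schema).
#' @return A `wlogit_normalized`: `beta` and `cov` on the expanded
#'   one-column-per-category scale, `cols` metadata, and the linear map `T`
#'   with `T %*% fit$beta == beta`.
#' @export
normalize_categorical <- function(fit, design) {
  stopifnot(inherits(fit, "wlogit"), inherits(design, "design_matrix"))
  if (length(fit$beta) != ncol(design$X)) {
    abort("Fit and design dimensions disagree.", class = "nd_contract_error")
  }
  ex <- expand_design(design)
  T <- normalization_matrix(design$groups, length(fit$beta), ex$cols)
  beta_n <- drop(T %*% fit$beta)
  names(beta_n) <- ex$cols$column
  cov_n <- T %*% fit$cov %*% t(T)
  dimnames(cov_n) <- list(ex$cols$column, ex$cols$column)
  structure(
    list(beta = beta_n, cov = cov_n, cols = ex$cols, groups = ex$groups,
         T = T, parent = fit, survey = fit$survey),
    class = "wlogit_normalized"
  )
}

#' @export
print.wlogit_normalized <- function(x, ...) {
  cat("<wlogit_normalized> survey ", x$survey, ": ", length(x$beta),
      " deviation-coded coefficients\n", sep = "")
  print(round(x$beta, 4))
  invisible(x)
}
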