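#' Percentage contribution of a component to a total
#'
#' @param component Numeric vector of component estimates.
#' @param total Non-zero scalar total.
#' @return `100 * component / total`.
#' @export
pct_contribution <- function(component, total) {
  if (!is.numeric(component) || !is.numeric(total) || length(total) != 1L) {
    abort("`component` must be numeric and `total` a scalar.",
          class = "nd_invalid_input")
  }
  if (!is.finite(total) || total == 0) {
    abort("Percentage contribution is undefined for a zero total.",
          class = "nd_undefined_pct")
  }
  100 * component / total
}

check_design_compat <- function(design_a, design_b) {
  if (!identical(colnames(design_a$X), colnames(design_b$X)) ||
      !identical(design_a$groups, design_b$groups)) {
    abort("The two surveys' designs must share column order and variable groups.",
          class = "nd_schema_error")
  }
}

# E/C totals on the probability scale.
# A = comparison (later) survey, B = baseline (earlier) survey:
#   E = meanW_A[logistic(X_A b_A)] - meanW_B[logistic(X_B b_A)]
#   C = meanW_B[logistic(X_B b_A)] - meanW_B[logistic(X_B b_B)]
ec_totals <- function(XA, wA, XB, wB, bA, bB) {
  mA  <- weighted_mean_p(XA, bA, wA)
  mBA <- weighted_mean_p(XB, bA, wB)
  mB  <- weighted_mean_p(XB, bB, wB)
  c(E = mA - mBA, C = mBA - mB)
}

# analytic gradients of (E, C) wrt stacked (b_A, b_B)
ec_gradients <- function(XA, wA, XB, wB, bA, bB) {
  K <- length(bA)
  dmean <- function(X, w, b) {
    p <- plogis(drop(X %*% b))
    drop(crossprod(X, w * p * (1 - p))) / sum(w)
  }
  gE <- c(dmean(XA, wA, bA) - dmean(XB, wB, bA), rep(0, K))
  gC <- c(dmean(XB, wB, bA), -dmean(XB, wB, bB))
  rbind(E = gE, C = gC)
}

# per-column detail terms for a stacked parameter vector theta = c(bA, bB),
# on the (possibly expanded/normalised) column scale defined by Tm, xbars
detail_terms <- function(theta, K, XA, wA, XB, wB, Tm, xbarA, xbarB) {
  bA <- theta[seq_len(K)]
  bB <- theta[K + seq_len(K)]
  tot <- ec_totals(XA, wA, XB, wB, bA, bB)
  bAe <- drop(Tm %*% bA)
  bBe <- drop(Tm %*% bB)
  dx <- xbarA - xbarB
  numE <- dx * bAe
  numC <- xbarB * (bAe - bBe)
  denE <- sum(numE)
  denC <- sum(numC)
  shareE <- if (abs(denE) > 0) numE / denE else numE * 0
  shareC <- if (abs(denC) > 0) numC / denC else numC * 0
  unname(c(tot[["E"]] * shareE, tot[["C"]] * shareC))
}

#' Decompose the change in prevalence between two fitted surveys
#'
#' Splits the difference in weighted mean predicted underweight probability
#' between a comparison survey A and a baseline survey B into an endowment
#' component E (difference in covariate composition, evaluated at A's
#' coefficients) and a coefficient component C (difference in coefficients,
#' evaluated at B's composition), on the probability scale:
#' \deqn{E = \bar F(X_A \beta_A) - \bar F(X_B \beta_A), \quad
#'       C = \bar F(X_B \beta_A) - \bar F(X_B \beta_B),}
#' with \eqn{\bar F} the weighted mean of the inverse logit over the named
#' survey's rows. Detailed per-category contributions use first-order
#' linearisation shares \eqn{E_k = E\,(\bar x^A_k - \bar x^B_k)\beta_{A,k} /
#' (\bar x^A - \bar x^B)^\top \beta_A} and \eqn{C_k = C\,\bar
#' x^B_k(\beta_{A,k} - \beta_{B,k}) / \bar x^{B\top}(\beta_A - \beta_B)}
#' (the intercept contributes to C only). With `normalize = TRUE`
#' (default) the detail is computed on deviation-normalised coefficients so
#' per-category rows do not depend on reference-category choice. Standard
#' errors are delta-method: analytic gradients for E and C, central finite
#' differences (step 1e-6) for the detail terms, with the two surveys'
#' coefficient covariances treated as independent (block-diagonal).
#'
#' @param design_a,design_b `design_matrix` objects for the comparison (A,
#'   later) and baseline (B, earlier) surveys; must share columns.
#' @param fit_a,fit_b `wlogit` fits on those designs.
#' @param detail Compute per-category detailed contributions? (default TRUE)
#' @param normalize Apply deviation normalisation to the detail? (default TRUE)
#' @param conf_level Confidence level for reported intervals.
#' @return A `decomposition` object; see [tidy.decomposition()] and
#'   [glance.decomposition()].
#' @export
decompose_fits <- function(design_a, design_b, fit_a, fit_b,
                           detail = TRUE, normalize = TRUE,
                           conf_level = 0.95) {
  stopifnot(inherits(design_a, "design_matrix"), inherits(design_b, "design_matrix"),
            inherits(fit_a, "wlogit"), inherits(fit_b, "wlogit"))
  check_design_compat(design_a, design_b)
  if (!identical(names(fit_a$beta), colnames(design_a$X)) ||
      !identical(names(fit_b$beta), colnames(design_b$X))) {
    abort("Fits do not correspond to the supplied designs.",
          class = "nd_contract_error")
  }
  if (!is.matrix(fit_a[["cov"]]) || !is.matrix(fit_b[["cov"]])) {
    abort("Fits must carry covariance matrices.", class = "nd_contract_error")
  }
  XA <- design_a$X; wA <- design_a$w
  XB <- design_b$X; wB <- design_b$w
  bA <- fit_a$beta; bB <- fit_b$beta
  K <- length(bA)

  tot <- ec_totals(XA, wA, XB, wB, bA, bB)
  E <- tot[["E"]]; C <- tot[["C"]]
  total <- E + C

  V <- matrix(0, 2 * K, 2 * K)
  V[seq_len(K), seq_len(K)] <- fit_a$cov
  V[K + seq_len(K), K + seq_len(K)] <- fit_b$cov
  G <- ec_gradients(XA, wA, XB, wB, bA, bB)
  ec_se <- sqrt(pmax(diag(G %*% V %*% t(G)), 0))

  pct_defined <- abs(total) > 1e-10
  res <- structure(
    list(total = total, E = E, C = C,
         E_se = ec_se[[1]], C_se = ec_se[[2]],
         pct_E = if (pct_defined) 100 * E / total else NA_real_,
         pct_C = if (pct_defined) 100 * C / total else NA_real_,
         detail = NULL, normalize = normalize, conf_level = conf_level,
         baseline = design_b$survey, comparison = design_a$survey,
         n_obs = c(comparison = nrow(XA), baseline = nrow(XB))),
    class = "decomposition"
  )
  if (!detail) return(res)

  if (normalize) {
    exA <- expand_design(design_a)
    cols <- exA$cols
    Tm <- normalization_matrix(design_a$groups, K, cols)
    XAe <- exA$X
    XBe <- expand_design(design_b)$X
  } else {
    cols <- design_a$cols
    Tm <- diag(K)
    XAe <- XA
    XBe <- XB
  }
  xbarA <- drop(crossprod(XAe, wA)) / sum(wA)
  xbarB <- drop(crossprod(XBe, wB)) / sum(wB)
  bAe <- drop(Tm %*% bA); bBe <- drop(Tm %*% bB)
  denE <- sum((xbarA - xbarB) * bAe)
  denC <- sum(xbarB * (bAe - bBe))
  if (abs(denE) < 1e-12 && abs(E) > 1e-10) {
    abort("Degenerate endowment allocation: linearisation denominator ~ 0 while E is not.",
          class = "nd_degenerate_allocation")
  }
  if (abs(denC) < 1e-12 && abs(C) > 1e-10) {
    abort("Degenerate coefficient allocation: linearisation denominator ~ 0 while C is not.",
          class = "nd_degenerate_allocation")
  }

  theta <- c(bA, bB)
  terms0 <- detail_terms(theta, K, XA, wA, XB, wB, Tm, xbarA, xbarB)
  nterm <- length(terms0)            # 2 * Ke
  Ke <- nterm / 2L

  # delta-method SEs for detail terms via central finite differences
  h <- 1e-6
  J <- matrix(0, nterm, 2 * K)
  for (j in seq_len(2 * K)) {
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + h
    tm[j] <- tm[j] - h
    J[, j] <- (detail_terms(tp, K, XA, wA, XB, wB, Tm, xbarA, xbarB) -
                 detail_terms(tm, K, XA, wA, XB, wB, Tm, xbarA, xbarB)) / (2 * h)
  }
  term_se <- sqrt(pmax(diag(J %*% V %*% t(J)), 0))

  E_k <- terms0[seq_len(Ke)]
  C_k <- terms0[Ke + seq_len(Ke)]
  res$detail <- tibble::tibble(
    variable = cols$variable,
    category = cols$category,
    E_k = E_k,
    E_k_se = term_se[seq_len(Ke)],
    E_k_pct = if (pct_defined) 100 * E_k / total else NA_real_,
    C_k = C_k,
    C_k_se = term_se[Ke + seq_len(Ke)],
    C_k_pct = if (pct_defined) 100 * C_k / total else NA_real_
  )
  res
}

#' Decompose the change in underweight prevalence between two surveys
#'
#' High-level wrapper: builds the design matrices, fits the survey-weighted
#' logistic model in each survey, and runs the detailed decomposition.
#'
#' @param baseline,comparison `survey_dataset` objects for the earlier
#'   (baseline, B) and later (comparison, A) surveys, sharing one schema.
#' @param cov_type Covariance estimator passed to [fit_wlogit()].
#' @inheritParams decompose_fits
#' @return A `decomposition` object (with the two fits attached as
#'   `$fit_baseline`, `$fit_comparison`).
#' @examples
#' cfg <- default_generator_config(seed = 1, n_per_survey = 2000)
#' ds <- generate_surveys(cfg)
#' dec <- decompose_change(ds[["2005"]], ds[["2016"]])
#' glance(dec)
#' @export
decompose_change <- function(baseline, comparison, detail = TRUE,
                             normalize = TRUE, cov_type = "sandwich",
                             conf_level = 0.95) {
  stopifnot(inherits(baseline, "survey_dataset"),
            inherits(comparison, "survey_dataset"))
  if (!identical(unclass(baseline$schema), unclass(comparison$schema))) {
    abort("Baseline and comparison surveys must share one schema.",
          class = "nd_schema_error")
  }
  db <- build_design(baseline)
  da <- build_design(comparison)
  fb <- fit_wlogit(db, cov_type = cov_type)
  fa <- fit_wlogit(da, cov_type = cov_type)
  res <- decompose_fits(da, db, fa, fb, detail = detail,
                        normalize = normalize, conf_level = conf_level)
  res$fit_baseline <- fb
  res$fit_comparison <- fa
  res
}

#' @export
print.decomposition <- function(x, digits = 5, ...) {
  cat("<decomposition> ", x$baseline, " (baseline) -> ", x$comparison,
      " (comparison), probability scale\n", sep = "")
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  cat("  total change: ", fmt(x$total), "\n", sep = "")
  cat("  endowments E: ", fmt(x$E), " (se ", fmt(x$E_se), ", ",
      formatC(x$pct_E, digits = 2, format = "f"), "%)\n", sep = "")
  cat("  coefficients C: ", fmt(x$C), " (se ", fmt(x$C_se), ", ",
      formatC(x$pct_C, digits = 2, format = "f"), "%)\n", sep = "")
  if (!is.null(x$detail)) {
    cat("  detail: ", nrow(x$detail), " rows (normalised: ",
        x$normalize, ")\n", sep = "")
  }
  invisible(x)
}

#' Tidy a decomposition's detailed contributions
#'
#' @param x A `decomposition`.
#' @param ... Unused.
#' @return A tibble with one row per covariate category (and the intercept
#'   row), estimates, delta-method standard errors, confidence bounds and
#'   percentage shares for both components.
#' @exportS3Method generics::tidy
tidy.decomposition <- function(x, ...) {
  if (is.null(x$detail)) {
    abort("This decomposition was computed without detail.",
          class = "nd_contract_error")
  }
  z <- qnorm(1 - (1 - x$conf_level) / 2)
  dplyr::mutate(
    x$detail,
    E_conf.low = .data$E_k - z * .data$E_k_se,
    E_conf.high = .data$E_k + z * .data$E_k_se,
    C_conf.low = .data$C_k - z * .data$C_k_se,
    C_conf.high = .data$C_k + z * .data$C_k_se
  )
}

#' One-row summary of a decomposition
#'
#' @param x A `decomposition`.
#' @param ... Unused.
#' @return A one-row tibble with the total change, E, C, their standard
#'   errors and percentage shares.
#' @exportS3Method generics::glance
glance.decomposition <- function(x, ...) {
  tibble::tibble(
    baseline = x$baseline, comparison = x$comparison,
    total = x$total, E = x$E, E_se = x$E_se, pct_E = x$pct_E,
    C = x$C, C_se = x$C_se, pct_C = x$pct_C,
    normalized = x$normalize
  )
}

# report-shaped table (one row per category + totals row)
decomposition_report <- function(x) {
  stopifnot(inherits(x, "decomposition"))
  if (is.null(x$detail)) {
    abort("Report requires a detailed decomposition.", class = "nd_contract_error")
  }
  z <- qnorm(1 - (1 - x$conf_level) / 2)
  d <- x$detail
  body <- tibble::tibble(
    variable = ifelse(d$variable == "(Intercept)", "Constant", d$variable),
    category = d$category,
    E = d$E_k, E_CI_low = d$E_k - z * d$E_k_se, E_CI_high = d$E_k + z * d$E_k_se,
    E_pct = d$E_k_pct,
    C = d$C_k, C_CI_low = d$C_k - z * d$C_k_se, C_CI_high = d$C_k + z * d$C_k_se,
    C_pct = d$C_k_pct
  )
  totals <- tibble::tibble(
    variable = "Total", category = NA_character_,
    E = x$E, E_CI_low = x$E - z * x$E_se, E_CI_high = x$E + z * x$E_se,
    E_pct = x$pct_E,
    C = x$C, C_CI_low = x$C - z * x$C_se, C_CI_high = x$C + z * x$C_se,
    C_pct = x$pct_C
  )
  dplyr::bind_rows(body, totals)
}

#' Plot detailed decomposition contributions
#'
#' Horizontal bars of the per-category endowment (E) and coefficient (C)
#' contributions to the change in prevalence.
#'
#' @param object A `decomposition` with detail.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.decomposition <- function(object, ...) {
  d <- tidy(object)
  long <- tidyr::pivot_longer(
    dplyr::mutate(d, label = paste(.data$variable,
                                   dplyr::coalesce(.data$category, ""))),
    cols = c("E_k", "C_k"), names_to = "component", values_to = "contribution"
  )
  long$component <- factor(long$component, levels = c("E_k", "C_k"),
                           labels = c("Endowments (E)", "Coefficients (C)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$contribution, y = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~component) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(
      x = "Contribution to change in prevalence (probability scale)",
      y = NULL,
      title = paste0("Decomposition: ", object$baseline, " to ",
                     object$comparison)
    )
}
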