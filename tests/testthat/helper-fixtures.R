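# shared builders for tiny in-code fixtures

# a design_matrix built directly from its parts (bypasses build_design so
# degenerate but legal decomposition inputs, e.g. a constant covariate in
# one survey, can be constructed for worked examples)
make_design <- function(X, y, w, schema, survey) {
  groups <- list()
  cols <- list(tibble::tibble(column = "(Intercept)",
                              variable = "(Intercept)",
                              category = NA_character_))
  k <- 1L
  for (v in names(schema)) {
    nonref <- schema[[v]][-1]
    groups[[v]] <- k + seq_along(nonref)
    cols[[length(cols) + 1L]] <- tibble::tibble(
      column = paste(v, nonref, sep = "."), variable = v, category = nonref)
    k <- k + length(nonref)
  }
  cols <- dplyr::bind_rows(cols)
  colnames(X) <- cols$column
  structure(list(X = X, y = y, w = w, cols = cols, groups = groups,
                 schema = schema, survey = survey),
            class = "design_matrix")
}

# a wlogit object with prescribed coefficients and covariance
make_fit <- function(beta, design, cov = NULL) {
  names(beta) <- colnames(design$X)
  if (is.null(cov)) cov <- matrix(0, length(beta), length(beta))
  dimnames(cov) <- list(names(beta), names(beta))
  structure(list(beta = beta, cov = cov, n_obs = nrow(design$X),
                 converged = TRUE, iterations = 0L, loglik = NA_real_,
                 cov_type = "fixed", cols = design$cols,
                 groups = design$groups, schema = design$schema,
                 survey = design$survey),
            class = "wlogit")
}

# small two-survey generator config over a compact schema
small_config <- function(seed = 1L, n = 1500L,
                         beta_b = c(-0.5, 0.6, -0.4, 0.3),
                         beta_a = c(-0.9, 0.8, -0.2, 0.5)) {
  schema <- survey_schema(
    wealth = c("Poor", "Middle", "Rich"),
    residence = c("Urban", "Rural")
  )
  generator_config(
    schema = schema, labels = c("B", "A"), n_per_survey = n,
    composition = list(
      B = list(wealth = c(0.5, 0.3, 0.2), residence = c(0.4, 0.6)),
      A = list(wealth = c(0.35, 0.3, 0.35), residence = c(0.55, 0.45))
    ),
    beta = list(B = beta_b, A = beta_a),
    weight_sd = 0.4, seed = seed
  )
}

# independent enumeration oracle for ground truth (kept free of the
# package's ground_truth() implementation; brute force over all cells)
oracle_ground_truth <- function(config, baseline, comparison) {
  schema <- config$schema
  grid <- expand.grid(schema, stringsAsFactors = FALSE)
  p_of <- function(lab) {
    p <- rep(1, nrow(grid))
    for (v in names(schema)) {
      pv <- config$composition[[lab]][[v]]
      names(pv) <- schema[[v]]
      p <- p * pv[grid[[v]]]
    }
    unname(p)
  }
  eta_of <- function(lab) {
    b <- config$beta[[lab]]
    eta <- rep(b[1], nrow(grid))
    k <- 1L
    for (v in names(schema)) {
      for (cat in schema[[v]][-1]) {
        k <- k + 1L
        eta <- eta + b[k] * (grid[[v]] == cat)
      }
    }
    eta
  }
  FA <- plogis(eta_of(comparison)); FB <- plogis(eta_of(baseline))
  pA <- p_of(comparison); pB <- p_of(baseline)
  list(E = sum((pA - pB) * FA), C = sum(pB * (FA - FB)),
       prev = c(baseline = sum(pB * FB), comparison = sum(pA * FA)))
}

# grouped 2x2 weighted-logit fixture: cell weights act as frequencies
design_2x2 <- function(n11, n10, n01, n00) {
  # x = 1: n11 events / n10 non-events; x = 0: n01 events / n00 non-events
  schema <- survey_schema(x = c("zero", "one"))
  make_design(
    X = cbind(1, c(1, 1, 0, 0)),
    y = c(1, 0, 1, 0),
    w = c(n11, n10, n01, n00),
    schema = schema, survey = "grouped"
  )
}
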