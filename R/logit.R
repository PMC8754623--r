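# numerically safe log(1 + exp(x))
log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 0
  out[big] <- x[big] + log1p(exp(-x[big]))
  out[!big] <- log1p(exp(x[!big]))
  out
}

#' Survey-weighted logistic regression
#'
#' Maximises the probability-weighted Bernoulli log-likelihood
#' \eqn{\sum_i w_i [y_i \log p_i + (1-y_i)\log(1-p_i)]} with
#' \eqn{p_i = \mathrm{logit}^{-1}(x_i^\top\beta)} by Newton-Raphson with
#' step-halving. Weights are treated as probability (pweight) weights:
#' point estimates solve the weighted score equations and the default
#' covariance is the sandwich estimator
#' \eqn{H^{-1} (\sum_i w_i^2 s_i s_i^\top) H^{-1}}; a model-based
#' \eqn{H^{-1}} and a cluster-robust variant are available.
#'
#' @param design A `design_matrix` from [build_design()].
#' @param cov_type One of `"sandwich"` (default), `"model"`, `"cluster"`.
#' @param cluster With `cov_type = "cluster"`, a length-N vector of cluster
#'   labels; scores are summed within clusters before the middle term.
#' @param max_iter Maximum Newton iterations (default 100).
#' @param tol Convergence tolerance on the maximum absolute weighted score
#'   component (default 1e-8).
#' @return A `wlogit` object: `beta` (named, intercept first), `cov`,
#'   `n_obs`, `converged`, `iterations`, `loglik`, plus the design's column
#'   metadata for downstream decomposition.
#' @export
fit_wlogit <- function(design, cov_type = c("sandwich", "model", "cluster"),
                       cluster = NULL, max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(design, "design_matrix"))
  cov_type <- match.arg(cov_type)
  X <- design$X; y <- design$y; w <- design$w
  if (!all(y %in% c(0, 1))) {
    abort("Outcome must be binary 0/1.", class = "nd_invalid_input")
  }
  if (any(w < 0) || sum(w) <= 0) {
    abort("Weights must be non-negative with positive sum.",
          class = "nd_invalid_input")
  }
  if (cov_type == "cluster") {
    if (is.null(cluster) || length(cluster) != nrow(X)) {
      abort("`cluster` must be a length-N vector for cov_type = \"cluster\".",
            class = "nd_contract_error")
    }
  }
  K <- ncol(X)

  wloglik <- function(beta) {
    eta <- drop(X %*% beta)
    sum(w * (y * eta - log1pexp(eta)))
  }
  # start at intercept = logit of weighted prevalence, slopes 0
  pbar <- sum(w * y) / sum(w)
  pbar <- min(max(pbar, 1e-10), 1 - 1e-10)
  beta <- c(qlogis(pbar), rep(0, K - 1L))
  ll <- wloglik(beta)
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    p <- plogis(drop(X %*% beta))
    score <- drop(crossprod(X, w * (y - p)))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    H <- crossprod(X, X * (w * p * (1 - p)))
    step <- tryCatch(solve(H, score), error = function(e) {
      abort("Singular weighted Hessian: collinear design columns.",
            class = "nd_collinearity_error", parent = e)
    })
    new_beta <- beta + step
    new_ll <- wloglik(new_beta)
    halvings <- 0L
    while ((!is.finite(new_ll) || new_ll < ll) && halvings < 10L) {
      halvings <- halvings + 1L
      step <- step / 2
      new_beta <- beta + step
      new_ll <- wloglik(new_beta)
    }
    improving <- is.finite(new_ll) && new_ll >= ll
    if (any(abs(new_beta) > 30) && improving) {
      abort("Apparent separation: a coefficient exceeded 30 on the logit scale while the likelihood was still improving.",
            class = "nd_separation_error")
    }
    beta <- new_beta
    ll <- new_ll
  }
  if (!converged) {
    p <- plogis(drop(X %*% beta))
    score <- drop(crossprod(X, w * (y - p)))
    if (max(abs(score)) < tol) converged <- TRUE
  }
  if (!converged) {
    abort(
      paste0("Weighted logistic fit did not converge in ", max_iter,
             " iterations (max |score| = ",
             format(max(abs(score)), digits = 3), ")."),
      class = "nd_convergence_error",
      beta_last = beta
    )
  }

  p <- plogis(drop(X %*% beta))
  H <- crossprod(X, X * (w * p * (1 - p)))
  Hi <- tryCatch(solve(H), error = function(e) {
    abort("Singular weighted Hessian at the optimum.",
          class = "nd_collinearity_error", parent = e)
  })
  S <- X * (w * (y - p))            # row scores, weight included
  V <- switch(cov_type,
    model = Hi,
    sandwich = Hi %*% crossprod(S) %*% Hi,
    cluster = {
      Sc <- rowsum(S, group = as.character(cluster))
      Hi %*% crossprod(Sc) %*% Hi
    }
  )
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)

  structure(
    list(beta = beta, cov = V, n_obs = nrow(X), converged = converged,
         iterations = iter, loglik = ll, cov_type = cov_type,
         cols = design$cols, groups = design$groups, schema = design$schema,
         survey = design$survey),
    class = "wlogit"
  )
}

#' Weighted mean predicted probability
#'
#' Applies the inverse-logit row-wise and averages with the design's
#' sampling weights: \eqn{\sum_i w_i \mathrm{logit}^{-1}(x_i^\top\beta) /
#' \sum_i w_i}. With the fit's own design this equals the weighted observed
#' prevalence (intercept score equation), which is the identity the
#' decomposition totals rest on.
#'
#' @param fit A `wlogit`.
#' @param design A `design_matrix` with the same columns as the fit.
#' @return A single numeric probability.
#' @export
predict_mean <- function(fit, design) {
  stopifnot(inherits(fit, "wlogit"), inherits(design, "design_matrix"))
  if (ncol(design$X) != length(fit$beta) ||
      !identical(colnames(design$X), names(fit$beta))) {
    abort("Design columns do not match the fitted coefficients.",
          class = "nd_contract_error")
  }
  weighted_mean_p(design$X, fit$beta, design$w)
}

weighted_mean_p <- function(X, beta, w) {
  sum(w * plogis(drop(X %*% beta))) / sum(w)
}

#' @export
print.wlogit <- function(x, ...) {
  cat("<wlogit> survey ", x$survey, ": ", length(x$beta), " coefficients, ",
      x$n_obs, " obs, ", x$iterations, " iterations (",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  print(round(x$beta, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.wlogit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$cov))
  out <- tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(se),
    statistic = unname(x$beta / se),
    p.value = 2 * pnorm(-abs(unname(x$beta / se)))
  )
  if (conf.int) {
    z <- qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  out
}

#' @exportS3Method generics::glance
glance.wlogit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, logLik = x$loglik, iterations = x$iterations,
    converged = x$converged, cov_type = x$cov_type
  )
}
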