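test_that("identical surveys and fits give a null decomposition", {
  cfg <- small_config(seed = 21, n = 600)
  d <- build_design(generate_survey(cfg, "B"))
  f <- fit_wlogit(d)
  dec <- decompose_fits(d, d, f, f)
  expect_equal(dec$E, 0, tolerance = 1e-12)
  expect_equal(dec$C, 0, tolerance = 1e-12)
  expect_equal(dec$total, 0, tolerance = 1e-12)
  expect_true(is.na(dec$pct_E))  # shares undefined at a ~0 total
})

test_that("equal coefficients force C (and every C_k) to zero", {
  cfg <- small_config(seed = 22, n = 800)
  dB <- build_design(generate_survey(cfg, "B"))
  dA <- build_design(generate_survey(cfg, "A"))
  fB <- fit_wlogit(dB)
  f_same <- make_fit(unname(fB$beta), dA, cov = fB$cov)
  dec <- decompose_fits(dA, dB, f_same, fB)
  expect_equal(dec$C, 0, tolerance = 1e-12)
  expect_equal(dec$detail$C_k, rep(0, nrow(dec$detail)), tolerance = 1e-12)
})

test_that("two-row worked example matches the hand evaluation", {
  # B rows x = (0, 1), weights (1, 1); A rows x = (1, 1);
  # beta_B = (0, 0), beta_A = (0, 1):
  #   E = logistic(1) - (logistic(0) + logistic(1))/2
  #   C = (logistic(0) + logistic(1))/2 - 0.5
  sch <- survey_schema(x = c("lo", "hi"))
  dB <- make_design(cbind(1, c(0, 1)), c(0, 1), c(1, 1), sch, "B")
  dA <- make_design(cbind(1, c(1, 1)), c(1, 1), c(1, 1), sch, "A")
  fB <- make_fit(c(0, 0), dB)
  fA <- make_fit(c(0, 1), dA)
  dec <- decompose_fits(dA, dB, fA, fB, normalize = FALSE)
  expect_equal(dec$E, plogis(1) - (0.5 + plogis(1)) / 2, tolerance = 1e-12)
  expect_equal(dec$C, (0.5 + plogis(1)) / 2 - 0.5, tolerance = 1e-12)
  expect_equal(dec$E, 0.1155293, tolerance = 1e-7)
  expect_equal(dec$C, 0.1155293, tolerance = 1e-7)
  expect_equal(dec$total, 0.2310586, tolerance = 1e-7)
  # detail: intercept means equal => E entirely on the covariate column;
  # intercept coefficients equal => C entirely on the covariate column
  det <- dec$detail
  expect_equal(det$E_k[det$variable == "(Intercept)"], 0, tolerance = 1e-12)
  expect_equal(det$E_k[det$variable == "x"], dec$E, tolerance = 1e-12)
  expect_equal(det$C_k[det$variable == "(Intercept)"], 0, tolerance = 1e-12)
  expect_equal(det$C_k[det$variable == "x"], dec$C, tolerance = 1e-12)
})

test_that("deviation normalisation centres effects and preserves the linear predictor", {
  # binary variable with effect (ref 0, nonref b): normalised (-b/2, +b/2),
  # intercept shifted by b/2
  sch <- survey_schema(x = c("lo", "hi"))
  d <- make_design(cbind(1, c(0, 1, 1, 0)), c(0, 1, 1, 0), rep(1, 4), sch, "s")
  b <- 0.8
  f <- make_fit(c(-0.3, b), d)
  nf <- normalize_categorical(f, d)
  expect_equal(unname(nf$beta),
               c(-0.3 + b / 2, -b / 2, b / 2), tolerance = 1e-12)
  # already-centred effects are a fixed point (up to the expanded coding)
  f2 <- make_fit(c(0.1, 0), d)
  nf2 <- normalize_categorical(f2, d)
  expect_equal(unname(nf2$beta), c(0.1, 0, 0), tolerance = 1e-12)
  # linear predictor preserved on a random multi-variable design
  cfg <- small_config(seed = 23, n = 500)
  dd <- build_design(generate_survey(cfg, "A"))
  ff <- fit_wlogit(dd)
  nn <- normalize_categorical(ff, dd)
  ex <- nutridecomp:::expand_design(dd)
  expect_equal(drop(ex$X %*% nn$beta), drop(dd$X %*% ff$beta),
               tolerance = 1e-12)
  # per-variable deviation effects sum to zero
  for (g in nn$groups) expect_equal(sum(nn$beta[g]), 0, tolerance = 1e-12)
})

test_that("detail terms always recombine to the component totals", {
  set.seed(24)
  for (norm in c(TRUE, FALSE)) {
    cfg <- small_config(seed = 25, n = 700)
    ds <- generate_surveys(cfg)
    dec <- decompose_change(ds$B, ds$A, normalize = norm)
    expect_equal(dec$E + dec$C, dec$total, tolerance = 1e-10)
    expect_equal(sum(dec$detail$E_k), dec$E, tolerance = 1e-10)
    expect_equal(sum(dec$detail$C_k), dec$C, tolerance = 1e-10)
    expect_equal(dec$pct_E + dec$pct_C, 100, tolerance = 1e-8)
    expect_equal(sum(dec$detail$E_k_pct) + sum(dec$detail$C_k_pct), 100,
                 tolerance = 1e-8)
  }
})

test_that("single binary covariate: one-term allocation exhausts the totals", {
  sch <- survey_schema(x = c("no", "yes"))
  cfg <- generator_config(
    sch, c("B", "A"), 800,
    composition = list(B = list(x = c(0.6, 0.4)), A = list(x = c(0.3, 0.7))),
    beta = list(B = c(-0.4, 0.5), A = c(-0.8, 1.0)), seed = 26)
  ds <- generate_surveys(cfg)
  dec <- decompose_change(ds$B, ds$A, normalize = FALSE)
  det <- dec$detail
  expect_equal(det$E_k[det$variable == "x"], dec$E, tolerance = 1e-12)
  expect_equal(det$C_k[det$variable == "(Intercept)"] +
                 det$C_k[det$variable == "x"], dec$C, tolerance = 1e-12)
})

test_that("delta-method machinery: zero coefficient covariance gives zero SEs", {
  sch <- survey_schema(x = c("lo", "hi"))
  dB <- make_design(cbind(1, c(0, 1, 0, 1)), c(0, 1, 1, 0), rep(1, 4), sch, "B")
  dA <- make_design(cbind(1, c(0, 1, 1, 1)), c(1, 1, 0, 1), rep(1, 4), sch, "A")
  fB <- make_fit(c(0.2, -0.5), dB)
  fA <- make_fit(c(-0.1, 0.4), dA)
  dec <- decompose_fits(dA, dB, fA, fB)
  expect_equal(dec$E_se, 0, tolerance = 1e-14)
  expect_equal(dec$C_se, 0, tolerance = 1e-14)
  expect_equal(dec$detail$E_k_se, rep(0, nrow(dec$detail)), tolerance = 1e-14)
})

test_that("E ignores the baseline fit's uncertainty (gradient wrt beta_B is zero)", {
  cfg <- small_config(seed = 27, n = 900)
  ds <- generate_surveys(cfg)
  dB <- build_design(ds$B); dA <- build_design(ds$A)
  fB <- fit_wlogit(dB); fA <- fit_wlogit(dA)
  dec1 <- decompose_fits(dA, dB, fA, fB, detail = FALSE)
  fB_inflated <- fB; fB_inflated$cov <- fB$cov * 1e6
  dec2 <- decompose_fits(dA, dB, fA, fB_inflated, detail = FALSE)
  expect_equal(dec1$E_se, dec2$E_se, tolerance = 1e-12)
  expect_true(dec2$C_se > dec1$C_se)
})

test_that("analytic E/C standard errors match a finite-difference delta method", {
  cfg <- small_config(seed = 28, n = 1200)
  ds <- generate_surveys(cfg)
  dB <- build_design(ds$B); dA <- build_design(ds$A)
  fB <- fit_wlogit(dB); fA <- fit_wlogit(dA)
  dec <- decompose_fits(dA, dB, fA, fB, detail = FALSE)
  K <- length(fA$beta)
  th <- c(fA$beta, fB$beta)
  f <- function(th) {
    bA <- th[seq_len(K)]; bB <- th[K + seq_len(K)]
    mA <- sum(dA$w * plogis(drop(dA$X %*% bA))) / sum(dA$w)
    mBA <- sum(dB$w * plogis(drop(dB$X %*% bA))) / sum(dB$w)
    mB <- sum(dB$w * plogis(drop(dB$X %*% bB))) / sum(dB$w)
    c(mA - mBA, mBA - mB)
  }
  h <- 1e-6
  J <- vapply(seq_along(th), function(j) {
    tp <- th; tm <- th; tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(2))
  V <- matrix(0, 2 * K, 2 * K)
  V[seq_len(K), seq_len(K)] <- fA$cov
  V[K + seq_len(K), K + seq_len(K)] <- fB$cov
  se_fd <- sqrt(diag(J %*% V %*% t(J)))
  expect_equal(dec$E_se, se_fd[1], tolerance = 1e-6)
  expect_equal(dec$C_se, se_fd[2], tolerance = 1e-6)
})

test_that("swapping the survey roles negates the total", {
  cfg <- small_config(seed = 29, n = 800)
  ds <- generate_surveys(cfg)
  dec_fwd <- decompose_change(ds$B, ds$A, detail = FALSE)
  dec_rev <- decompose_change(ds$A, ds$B, detail = FALSE)
  expect_equal(dec_fwd$total, -dec_rev$total, tolerance = 1e-12)
})

test_that("percentage contributions follow their definition and guard zero totals", {
  expect_equal(pct_contribution(-0.05, -0.25), 20)
  expect_equal(pct_contribution(0.7, 0.7), 100)
  expect_equal(pct_contribution(c(1, 3), 8), c(12.5, 37.5))
  expect_error(pct_contribution(0.1, 0), class = "nd_undefined_pct")
})

test_that("mismatched designs and missing covariances are contract errors", {
  cfg <- small_config(seed = 30, n = 300)
  ds <- generate_surveys(cfg)
  dB <- build_design(ds$B); dA <- build_design(ds$A)
  fB <- fit_wlogit(dB); fA <- fit_wlogit(dA)
  dA_cut <- dA; dA_cut$X <- dA$X[, 1:3]; dA_cut$groups <- list(wealth = 2:3)
  expect_error(decompose_fits(dA_cut, dB, fA, fB), class = "nd_schema_error")
  fA_nocov <- fA; fA_nocov$cov <- NULL
  expect_error(decompose_fits(dA, dB, fA_nocov, fB),
               class = "nd_contract_error")
})
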