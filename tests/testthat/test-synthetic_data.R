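test_that("generator config validation names the offending field", {
  sch <- survey_schema(res = c("Urban", "Rural"))
  comp_ok <- list(B = list(res = c(0.4, 0.6)), A = list(res = c(0.5, 0.5)))
  beta_ok <- list(B = c(0, 0), A = c(0, 1))

  expect_s3_class(
    generator_config(sch, c("B", "A"), 10, comp_ok, beta_ok),
    "generator_config")
  expect_error(
    generator_config(sch, c("B", "A"), 0, comp_ok, beta_ok),
    regexp = "n_per_survey", class = "nd_validation_error")
  expect_error(
    generator_config(sch, c("B", "A"), 10,
                     list(B = list(res = c(0.4, 0.7)), A = list(res = c(0.5, 0.5))),
                     beta_ok),
    regexp = "composition", class = "nd_validation_error")
  expect_error(
    generator_config(sch, c("B", "A"), 10, comp_ok,
                     list(B = c(0, 0, 0), A = c(0, 1))),
    regexp = "beta", class = "nd_validation_error")
  expect_error(
    generator_config(sch, c("B", "A"), 10, comp_ok, beta_ok,
                     outcome_mode = "waz-latent", waz_sigma = 0),
    regexp = "waz_sigma", class = "nd_validation_error")
})

test_that("identical seeds reproduce identical surveys; seeds differ across surveys", {
  cfg <- small_config(seed = 42, n = 400)
  d1 <- generate_survey(cfg, "A")
  d2 <- generate_survey(cfg, "A")
  expect_identical(d1$data, d2$data)
  db <- generate_survey(cfg, "B")
  expect_false(identical(d1$data$underweight, db$data$underweight))
  # a different config seed changes the draw
  cfg2 <- small_config(seed = 43, n = 400)
  expect_false(identical(generate_survey(cfg2, "A")$data, d1$data))
})

test_that("generated weighted prevalence converges to the anchor rate", {
  # intercept-only model at the 2005 anchor prevalence of 38%
  sch <- survey_schema(res = c("Urban", "Rural"))
  n <- 100000L
  cfg <- generator_config(
    sch, c("B", "A"), n,
    composition = list(B = list(res = c(0.5, 0.5)), A = list(res = c(0.5, 0.5))),
    beta = list(B = c(qlogis(0.38), 0), A = c(qlogis(0.38), 0)),
    weight_sd = 0.5, seed = 7
  )
  ds <- generate_survey(cfg, "B")
  prev <- sum(ds$data$weight * ds$data$underweight) / sum(ds$data$weight)
  # binomial Monte-Carlo SE, inflated for weight heterogeneity
  # (lognormal sdlog 0.5: E[w^2]/E[w]^2 = exp(0.25) => design effect ~ 1.28)
  se <- sqrt(0.38 * 0.62 * exp(0.5^2) / n)
  expect_lt(abs(prev - 0.38), 3 * se)
})

test_that("latent-WAZ construction reproduces the cell-level logistic model", {
  sch <- survey_schema(res = c("Urban", "Rural"))
  n <- 100000L
  beta <- c(-0.6, 0.9)
  cfg <- generator_config(
    sch, c("B", "A"), n,
    composition = list(B = list(res = c(0.5, 0.5)), A = list(res = c(0.5, 0.5))),
    beta = list(B = beta, A = beta),
    outcome_mode = "waz-latent", waz_sigma = 1.1, seed = 9
  )
  ds <- generate_survey(cfg, "B")
  d <- ds$data
  expect_true("waz" %in% names(d))
  expect_equal(d$underweight, as.integer(d$waz < -2))
  for (cat in c("Urban", "Rural")) {
    p_target <- plogis(beta[1] + beta[2] * (cat == "Rural"))
    rows <- d[d$res == cat, ]
    p_hat <- mean(rows$underweight)
    se <- sqrt(p_target * (1 - p_target) / nrow(rows))
    expect_lt(abs(p_hat - p_target), 3 * se)
  }
})

test_that("enumerated ground truth matches the hand-computed binary example", {
  # one binary covariate: p_A(1) = 0.6, p_B(1) = 0.4, beta_B = (0,0),
  # beta_A = (0,1); enumeration over the 2-cell space gives
  # E = 0.2 * (logistic(1) - logistic(0)), C = 0.4 * (logistic(1) - logistic(0))
  sch <- survey_schema(x = c("no", "yes"))
  cfg <- generator_config(
    sch, c("B", "A"), 10,
    composition = list(B = list(x = c(0.6, 0.4)), A = list(x = c(0.4, 0.6))),
    beta = list(B = c(0, 0), A = c(0, 1)), seed = 1
  )
  gt <- ground_truth(cfg, "B", "A")
  expect_equal(gt$E_true, 0.2 * (plogis(1) - 0.5), tolerance = 1e-12)
  expect_equal(gt$C_true, 0.4 * (plogis(1) - 0.5), tolerance = 1e-12)
  expect_equal(gt$E_true, 0.0462117157, tolerance = 1e-9)
  expect_equal(gt$C_true, 0.0924234314, tolerance = 1e-9)
  # against the independent brute-force oracle
  or <- oracle_ground_truth(cfg, "B", "A")
  expect_equal(gt$E_true, or$E, tolerance = 1e-14)
  expect_equal(gt$C_true, or$C, tolerance = 1e-14)
})

test_that("ground truth: identical coefficients kill C, identical composition kills E", {
  cfg_c0 <- small_config(beta_b = c(-0.5, 0.6, -0.4, 0.3),
                         beta_a = c(-0.5, 0.6, -0.4, 0.3))
  gt <- ground_truth(cfg_c0, "B", "A")
  expect_identical(gt$C_true, 0)
  same_comp <- list(wealth = c(0.5, 0.3, 0.2), residence = c(0.4, 0.6))
  cfg_e0 <- generator_config(
    cfg_c0$schema, c("B", "A"), 10,
    composition = list(B = same_comp, A = same_comp),
    beta = list(B = c(-0.5, 0.6, -0.4, 0.3), A = c(-0.9, 0.8, -0.2, 0.5)),
    seed = 1)
  expect_identical(ground_truth(cfg_e0, "B", "A")$E_true, 0)
})

test_that("ground-truth additivity holds for random configs and matches the oracle", {
  set.seed(202)
  for (i in 1:25) {
    sch <- survey_schema(a = c("a1", "a2", "a3"), b = c("b1", "b2"))
    rp <- function(k) { p <- runif(k, 0.2, 1); p / sum(p) }
    cfg <- generator_config(
      sch, c("B", "A"), 10,
      composition = list(B = list(a = rp(3), b = rp(2)),
                         A = list(a = rp(3), b = rp(2))),
      beta = list(B = runif(4, -1, 1), A = runif(4, -1, 1)),
      seed = i)
    gt <- ground_truth(cfg, "B", "A")
    expect_equal(gt$E_true + gt$C_true,
                 unname(gt$prevalence_true["A"] - gt$prevalence_true["B"]),
                 tolerance = 1e-12)
    or <- oracle_ground_truth(cfg, "B", "A")
    expect_equal(gt$E_true, or$E, tolerance = 1e-13)
    expect_equal(gt$C_true, or$C, tolerance = 1e-13)
  }
})

test_that("enumeration refuses covariate spaces above the cap", {
  sch <- survey_schema(a = letters[1:10], b = LETTERS[1:10], c = paste0("x", 1:10))
  cfg <- generator_config(
    sch, c("B", "A"), 10,
    composition = list(
      B = list(a = rep(0.1, 10), b = rep(0.1, 10), c = rep(0.1, 10)),
      A = list(a = rep(0.1, 10), b = rep(0.1, 10), c = rep(0.1, 10))),
    beta = list(B = rep(0, 28), A = rep(0, 28)), seed = 1)
  expect_error(ground_truth(cfg, "B", "A", cap = 500),
               class = "nd_validation_error")
})

test_that("default scenario hits its calibrated prevalence anchors exactly", {
  cfg <- default_generator_config(seed = 1, n_per_survey = 100)
  gt <- ground_truth(cfg, "2005", "2016")
  expect_equal(unname(gt$prevalence_true),
               c(0.38, 0.29, 0.24), tolerance = 1e-9)
  expect_equal(gt$E_true + gt$C_true, 0.24 - 0.38, tolerance = 1e-9)
})
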