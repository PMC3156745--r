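test_that("the linear predictor reproduces the hand-computed dot products", {
  beta <- reference_cox_coefs()
  s1 <- cox_score(beta, data.frame(T = 2, CD68 = 3, Gas6 = 1, H = 1, Notch3 = 3))
  expect_equal(s1$score, -5.54, tolerance = 1e-12)
  s2 <- cox_score(beta, data.frame(T = 1, CD68 = 4, Gas6 = 3, H = 1, Notch3 = 4))
  expect_equal(s2$score, -10.38, tolerance = 1e-12)
  # zero coefficients -> zero score for any patient
  s0 <- cox_score(setNames(numeric(0), character(0)),
                  data.frame(T = 3, CD68 = 1))
  expect_equal(s0$score, 0)
  expect_error(cox_score(beta, data.frame(T = 1)), "missing covariate")
})

test_that("the linear predictor is linear in the raw coding", {
  beta <- reference_cox_coefs()
  a <- data.frame(T = 2, CD68 = 3, Gas6 = 1, H = 1, Notch3 = 3)
  b <- data.frame(T = 1, CD68 = 1, Gas6 = 2, H = 1, Notch3 = 0)
  zero <- data.frame(T = 0, CD68 = 0, Gas6 = 0, H = 0, Notch3 = 0)
  expect_equal(cox_score(beta, a)$score + cox_score(beta, b)$score -
                 cox_score(beta, zero)$score,
               cox_score(beta, a + b)$score, tolerance = 1e-12)
})

test_that("cox risk classes follow the printed cut-offs", {
  expect_equal(as.character(classify_cox(-5.54, "binary")), "good")
  expect_equal(as.character(classify_cox(-5.5, "binary")), "good")
  expect_equal(as.character(classify_cox(-5.4, "binary")), "bad")
  expect_equal(as.character(classify_cox(-4.0, "three_class")), "high")
  expect_equal(as.character(classify_cox(-7, "three_class")), "low")
  expect_equal(as.character(classify_cox(-6.0, "three_class")), "intermediate")
  expect_equal(as.character(classify_cox(-4.5, "three_class")), "intermediate")
  # the worked patient falls in the printed intermediate band
  expect_equal(as.character(classify_cox(-5.54, "three_class")), "intermediate")
})

test_that("backward elimination recovers a two-group log hazard ratio of ln 2", {
  set.seed(61)
  n <- 500
  g <- rep(0:1, each = n / 2)
  tt <- rexp(n, rate = 0.03 * exp(log(2) * g))
  d <- data.frame(patient_id = as.character(1:n),
                  survival_time = tt, event = 1, M = g)
  coh <- as_cohort(d, list(variable_spec("M", 0:1)))
  fit <- fit_cox_backward(coh)
  expect_equal(unname(coef(fit)["M"]), log(2), tolerance = 0.15)
  # sign matches the group survival difference (group 1 dies faster)
  expect_gt(coef(fit)["M"], 0)
})

test_that("a null covariate is eliminated, leaving an empty model with a trace", {
  set.seed(62)
  n <- 500
  d <- data.frame(patient_id = as.character(1:n),
                  survival_time = rexp(n, 1 / 25) + 0.01, event = 1,
                  MMP2 = sample(1:4, n, replace = TRUE))
  coh <- as_cohort(d, list(variable_spec("MMP2", 1:4)))
  fit <- fit_cox_backward(coh)
  expect_length(coef(fit), 0)
  expect_equal(fit$trace$variable, "MMP2")
  expect_gt(fit$trace$p_value, 0.05)
  expect_equal(cox_score(fit, coh)$score, rep(0, n))
})

test_that("constant candidates and event-free cohorts are rejected", {
  d <- data.frame(patient_id = letters[1:6], survival_time = 1:6, event = 1,
                  M = rep(1L, 6))
  coh <- as_cohort(d, list(variable_spec("M", 0:1)))
  expect_error(fit_cox_backward(coh), "constant")
  d2 <- d; d2$event <- 0; d2$M <- rep(c(0L, 1L), 3)
  coh2 <- as_cohort(d2, list(variable_spec("M", 0:1)))
  expect_error(fit_cox_backward(coh2), "events")
})

test_that("elimination on the synthetic cohort is deterministic and ordered", {
  coh <- generate_cohort(simulation_config(n = 120, seed = 8,
                                           latent_rho = calibrated_rho()))
  f1 <- fit_cox_backward(coh)
  f2 <- fit_cox_backward(coh)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$trace, f2$trace)
  # every retained variable is Wald-significant in the final model
  if (length(coef(f1))) {
    sm <- summary(f1$fit)$coefficients
    expect_true(all(sm[, "Pr(>|z|)"] < 0.05))
  }
})
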