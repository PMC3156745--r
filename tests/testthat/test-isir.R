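test_that("worked patients score as the hand-computed oracle", {
  m <- reference_isir_model()
  p1 <- data.frame(T = 2, N = 0, M = 0, Gas6 = 1, CD68 = 3)
  p2 <- data.frame(T = 4, N = 2, M = 1, Gas6 = 1, CD68 = 2)
  # A = 0.275/1.33, P = 0.3175/0.63 -> 0.410; A = 0.940/1.33, P = 0.2375/0.63
  expect_equal(isir_score(m, p1)$isir, (0.275 / 1.33) / (0.3175 / 0.63),
               tolerance = 1e-12)
  expect_equal(isir_score(m, p1)$isir, 0.410, tolerance = 1e-3)
  expect_equal(isir_score(m, p2)$isir, 1.875, tolerance = 1e-3)
  # all aggressive values at scaled zero -> score 0
  p0 <- data.frame(T = 1, N = 0, M = 0, Gas6 = 2, CD68 = 2)
  m0 <- isir_model(aggressive = c(N = 0.41, M = 0.37),
                   protective = c(Gas6 = 0.31, CD68 = 0.32),
                   specs = default_variable_specs())
  expect_equal(isir_score(m0, p0)$isir, 0)
})

test_that("vectorized scorer equals the brute-force loop implementation", {
  set.seed(31)
  m <- reference_isir_model()
  for (i in 1:1000) {
    row <- data.frame(T = sample(1:4, 1), N = sample(0:3, 1),
                      M = sample(0:1, 1), Gas6 = sample(1:4, 1),
                      CD68 = sample(1:4, 1))
    expect_equal(isir_score(m, row)$isir, isir_bruteforce(m, row),
                 tolerance = 1e-12)
  }
})

test_that("ISIR is monotone in its covariates with fixed weights", {
  set.seed(32)
  m <- reference_isir_model()
  for (i in 1:1000) {
    row <- data.frame(T = sample(1:3, 1), N = sample(0:2, 1),
                      M = 0, Gas6 = sample(1:3, 1), CD68 = sample(1:3, 1))
    base <- isir_score(m, row)$isir
    up_aggr <- row; up_aggr$T <- row$T + 1
    expect_gte(isir_score(m, up_aggr)$isir, base)
    up_prot <- row; up_prot$Gas6 <- row$Gas6 + 1
    expect_lte(isir_score(m, up_prot)$isir, base)
  }
})

test_that("rescaling all weights on one side leaves the normalised score unchanged", {
  set.seed(33)
  specs <- default_variable_specs()
  for (c_ in c(0.1, 3, 42)) {
    m1 <- reference_isir_model()
    m2 <- isir_model(aggressive = c(T = 0.55, N = 0.41, M = 0.37) * c_,
                     protective = c(Gas6 = 0.31, CD68 = 0.32),
                     specs = specs)
    m3 <- isir_model(aggressive = c(T = 0.55, N = 0.41, M = 0.37),
                     protective = c(Gas6 = 0.31, CD68 = 0.32) * c_,
                     specs = specs)
    rows <- data.frame(T = sample(1:4, 25, TRUE), N = sample(0:3, 25, TRUE),
                       M = sample(0:1, 25, TRUE), Gas6 = sample(1:4, 25, TRUE),
                       CD68 = sample(1:4, 25, TRUE))
    expect_equal(isir_score(m2, rows)$isir, isir_score(m1, rows)$isir,
                 tolerance = 1e-12)
    expect_equal(isir_score(m3, rows)$isir, isir_score(m1, rows)$isir,
                 tolerance = 1e-12)
  }
})

test_that("scores are bounded by the extreme scaled aggressive/protective values", {
  set.seed(34)
  m <- reference_isir_model()
  rows <- data.frame(T = sample(1:4, 500, TRUE), N = sample(0:3, 500, TRUE),
                     M = sample(0:1, 500, TRUE), Gas6 = sample(1:4, 500, TRUE),
                     CD68 = sample(1:4, 500, TRUE))
  s <- isir_score(m, rows)$isir
  expect_true(all(s >= 0))
  expect_true(all(s <= 1 / 0.25))  # max scaled aggressive 1, min protective 1/4
  expect_true(all(is.finite(s)))
})

test_that("risk classes follow the printed presets with boundary handling", {
  expect_equal(as.character(classify_risk(0.20, "methods")), "low")
  expect_equal(as.character(classify_risk(0.25, "methods")), "low")
  expect_equal(as.character(classify_risk(0.30, "methods")), "intermediate")
  expect_equal(as.character(classify_risk(0.50, "methods")), "high")
  expect_equal(as.character(classify_risk(0.90, "table3")), "high")
  expect_equal(as.character(classify_risk(0.40, "table3")), "intermediate")
  expect_equal(as.character(classify_risk(0.80, "table3")), "intermediate")
  expect_equal(as.character(classify_risk(0.39, "table3")), "low")
  expect_error(classify_risk(-0.1), "non-negative")

  expect_equal(as.character(classify_binary(0.5)), "good")
  expect_equal(as.character(classify_binary(0.51)), "bad")
  expect_equal(as.character(classify_binary(0)), "good")
})

test_that("screening labels aggressive/protective/excluded per sign and significance", {
  coh <- toy_cohort()
  scr <- screen_variables(coh, alpha = 0.05, require_score = FALSE)
  expect_true(all(scr$role[scr$p_value < 0.05 & scr$r_s < 0] == "aggressive"))
  expect_true(all(scr$role[scr$p_value < 0.05 & scr$r_s > 0] == "protective"))
  expect_true(all(scr$role[scr$p_value >= 0.05] == "excluded"))
  expect_true(all(abs(scr$r_s) <= 1))
  expect_true(all(scr$p_value >= 0 & scr$p_value <= 1))
  # T decreases with survival by construction
  expect_equal(scr$role[scr$variable == "T"], "aggressive")
})

test_that("a perfectly anti-monotone candidate gets weight 1", {
  d <- data.frame(patient_id = letters[1:4], survival_time = (1:4) * 10,
                  event = 1, T = 4:1, Gas6 = 1:4)
  coh <- as_cohort(d, list(variable_spec("T", 1:4), variable_spec("Gas6", 1:4)))
  fit <- fit_isir(coh)
  expect_equal(fit$aggressive$variable, "T")
  expect_equal(fit$aggressive$weight, 1, tolerance = 1e-12)
  expect_equal(fit$protective$weight, 1, tolerance = 1e-12)
})

test_that("fitting fails loudly when no protective variable is significant", {
  set.seed(35)
  d <- data.frame(patient_id = sprintf("p%02d", 1:20),
                  survival_time = rexp(20, 1 / 20) + 1, event = 1,
                  T = rep(1:4, 5)[sample(20)],
                  Gas6 = sample(1:4, 20, TRUE))
  coh <- as_cohort(d, list(variable_spec("T", 1:4), variable_spec("Gas6", 1:4)))
  expect_error(fit_isir(coh), "protective")
  expect_error(fit_isir(coh), "undefined")
})

test_that("predict and coef expose the fitted model coherently", {
  coh <- toy_cohort()
  fit <- fit_isir(coh)
  sc <- predict(fit, coh)
  expect_s3_class(sc, "isir_scores")
  expect_equal(nrow(sc), nrow(coh$data))
  expect_equal(sc$isir, fit$fitted$isir)
  cf <- coef(fit)
  expect_true(all(cf[fit$aggressive$variable] < 0))
  expect_true(all(cf[fit$protective$variable] > 0))
  expect_error(isir_score(fit, data.frame(T = 1)), "missing covariate")
})
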