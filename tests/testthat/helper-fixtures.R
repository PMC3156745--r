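# Shared fixtures, built in code.

toy_specs <- function() {
  list(variable_spec("T", 1:4), variable_spec("N", 0:3),
       variable_spec("M", 0:1), variable_spec("Gas6", 1:4),
       variable_spec("CD68", 1:4))
}

# Small deterministic cohort: T/N/M fall and Gas6/CD68 rise with survival,
# strongly enough that they stay significant in every leave-one-out fold.
toy_cohort <- function() {
  tt <- c(4, 8, 11, 15, 20, 30, 40, 55, 61, 70, 80, 95)
  data <- data.frame(
    patient_id = sprintf("pt%02d", 1:12),
    survival_time = tt,
    event = c(1, 1, 1, 1, 1, 1, 1, 1, 0, 1, 0, 0),
    T = c(4, 4, 4, 3, 3, 3, 2, 2, 2, 1, 1, 1),
    N = c(3, 2, 3, 2, 1, 2, 1, 0, 0, 0, 0, 0),
    M = c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0),
    Gas6 = c(1, 1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4),
    CD68 = c(1, 2, 1, 2, 3, 2, 3, 4, 3, 4, 4, 4))
  as_cohort(data, toy_specs())
}

# Published-style weights used by the worked-score oracles.
reference_isir_model <- function(...) {
  isir_model(aggressive = c(T = 0.55, N = 0.41, M = 0.37),
             protective = c(Gas6 = 0.31, CD68 = 0.32),
             specs = default_variable_specs(), ...)
}

reference_cox_coefs <- function() {
  c(T = 0.88, CD68 = -1.60, Gas6 = -0.78, H = 0.68, Notch3 = -0.80)
}

# Default-config latent correlations, calibrated once per test run and
# reused (calibration is itself exercised in test-synthetic.R).
calibrated_rho <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(20240915)
      cache <<- calibrate_copula(default_targets(), default_margins())
    }
    cache
  }
})

# Brute-force AUC over all (positive, negative) pairs with half credit
# for ties; independent oracle for roc_auc().
auc_bruteforce <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  total <- 0
  for (a in sp) for (b in sn)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(sp) * length(sn))
}

# Brute-force ISIR with explicit loops; independent oracle for the
# vectorized scorer.
isir_bruteforce <- function(model, row) {
  num_n <- num_d <- 0
  for (k in seq_len(nrow(model$aggressive))) {
    a <- model$aggressive[k, ]
    num_n <- num_n + a$weight * row[[a$variable]] / a$divisor
    num_d <- num_d + a$weight
  }
  den_n <- den_d <- 0
  for (k in seq_len(nrow(model$protective))) {
    p <- model$protective[k, ]
    den_n <- den_n + p$weight * row[[p$variable]] / p$divisor
    den_d <- den_d + p$weight
  }
  num <- if (num_d > 0 && model$normalize) num_n / num_d else num_n
  den <- if (model$normalize) den_n / den_d else den_n
  num / den
}
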