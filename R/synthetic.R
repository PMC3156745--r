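#' Default marginal category probabilities for the simulated cohort
#'
#' Pooled covariate margins of the 63-patient NSCLC-style study population
#' the simulator emulates (e.g. metastasis present in 10/63 patients;
#' CD68 staining concentrated in grades 2--3).  Probabilities are aligned
#' with the admissible codes of [default_variable_specs()].
#'
#' @return named list of probability vectors (each summing to 1).
#' @export
default_margins <- function() {
  list(
    T      = c(15, 26, 18, 3) / 62,
    N      = c(31, 17, 11, 3) / 62,
    M      = c(53, 10) / 63,
    H      = c(31, 32) / 63,
    CD68   = c(0, 3, 60, 0) / 63,
    Gas6   = c(35, 24, 4, 0) / 63,
    Notch3 = c(0, 10, 53, 0) / 63,
    MMP2   = c(0, 20, 43, 0) / 63,
    Cox2   = c(0, 5, 58, 0) / 63
  )
}

#' Default target Spearman correlations with survival
#'
#' The covariate-survival rank correlations the generator is calibrated to:
#' strong negative values for the staging triple (T, N, M), moderate
#' positive values for the protective markers (Gas6, CD68), weak positive
#' values for Notch3 and Cox2 (non-significant at n = 63), and zero for
#' MMP2 and histology.
#'
#' @return named numeric vector.
#' @export
default_targets <- function() {
  c(T = -0.55, N = -0.41, M = -0.37, H = 0,
    CD68 = 0.32, Gas6 = 0.31, Notch3 = 0.23, MMP2 = 0, Cox2 = 0.25)
}

#' Configuration for the synthetic cohort generator
#'
#' The generator draws a latent Gaussian prognosis factor per patient and
#' per-variable latent normals correlated with it (one-factor Gaussian
#' copula), discretizes the latents to ordinal categories by
#' marginal-probability thresholds, draws an exponential survival time whose
#' own latent is correlated `survival_rho` with the prognosis factor (so
#' survival is driven by, but not a deterministic function of, the factor),
#' and applies administrative right-censoring.  Defaults emulate the
#' 63-patient study population: study-style covariate margins, the target
#' rank correlations of [default_targets()], median survival 25 months
#' (rate \eqn{\log 2 / 25}) and a 60-month censoring window, giving an
#' expected censored fraction of about 0.19 (~12/63) with all censored
#' follow-up at 60 months.
#'
#' @param n cohort size (default 63).
#' @param specs named list of [variable_spec()]s.
#' @param margins named list of per-variable category probabilities (same
#'   names/lengths as `specs`).
#' @param targets named numeric vector of target Spearman correlations
#'   between each variable and the (uncensored) survival time,
#'   `|target| < 1`.
#' @param median_survival median of the exponential survival distribution,
#'   months.
#' @param censor_window administrative censoring time, months (`Inf` for no
#'   censoring).
#' @param survival_rho copula correlation between the latent prognosis
#'   factor and the survival time's latent, in (0, 1].  Smaller values mean
#'   noisier survival given the factor.  The default 0.93 is the smallest
#'   round value under which every default target correlation remains
#'   attainable given its ordinal margins (the heavily skewed CD68 margin
#'   is the binding case).
#' @param seed integer RNG seed used by [generate_cohort()] (optional).
#' @param latent_rho optional pre-calibrated latent correlations
#'   ([calibrate_copula()]); calibrated on first use when `NULL`.
#' @return a list of class `sim_config`.
#' @export
simulation_config <- function(n = 63, specs = default_variable_specs(),
                              margins = default_margins(),
                              targets = default_targets(),
                              median_survival = 25, censor_window = 60,
                              survival_rho = 0.93,
                              seed = NULL, latent_rho = NULL) {
  specs <- as_spec_list(specs)
  if (n < 4) stop("simulation_config: n must be at least 4")
  if (!setequal(names(margins), names(specs)))
    stop("simulation_config: margins must be given for exactly the declared variables")
  if (!setequal(names(targets), names(specs)))
    stop("simulation_config: targets must be given for exactly the declared variables")
  for (nm in names(specs)) {
    p <- margins[[nm]]
    if (length(p) != length(specs[[nm]]$values))
      stop("simulation_config: margins for '", nm,
           "' must match the number of admissible values")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("simulation_config: margins for '", nm, "' must be non-negative and sum to 1")
    if (sum(p > 0) < 2L)
      stop("simulation_config: variable '", nm, "' needs at least two categories ",
           "with positive probability")
    if (abs(targets[[nm]]) >= 1)
      stop("simulation_config: |target correlation| must be < 1 for '", nm, "'")
  }
  stopifnot(median_survival > 0, censor_window > 0,
            survival_rho > 0, survival_rho <= 1)
  structure(list(n = as.integer(n), specs = specs,
                 margins = margins[names(specs)],
                 targets = targets[names(specs)],
                 median_survival = median_survival,
                 censor_window = censor_window,
                 survival_rho = survival_rho,
                 seed = seed, latent_rho = latent_rho),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> n = %d, %d variables, exp median %.0f mo, censor window %s mo\n",
              x$n, length(x$specs), x$median_survival,
              format(x$censor_window)))
  cat("  targets:", paste(sprintf("%s=%+.2f", names(x$targets), x$targets),
                          collapse = " "), "\n")
  invisible(x)
}

#' Calibrate latent copula correlations to target Spearman correlations
#'
#' Discretizing a latent normal onto few ordinal categories attenuates its
#' rank correlation with the continuous survival factor, so the latent
#' correlation needed to realize a target Spearman correlation is larger in
#' magnitude than the target itself, and heavily skewed margins cap what is
#' attainable at all.  No usable closed form covers tied ordinal margins,
#' so the mapping is inverted by pilot simulation: a large pilot sample of
#' the latent factor is drawn once and, for each variable, the latent
#' correlation is bisected (common random numbers make the realized Spearman
#' monotone and smooth in it) until the pilot Spearman correlation between
#' the discretized variable and the factor matches the target.  Targets
#' beyond the margin-limited maximum raise an error reporting the attainable
#' bound.
#'
#' @param targets named numeric vector of target Spearman correlations
#'   (versus uncensored survival time).
#' @param margins named list of category probabilities per variable.
#' @param survival_rho copula correlation between prognosis factor and the
#'   survival latent (see [simulation_config()]); the calibration is
#'   conditional on it.
#' @param n_pilot pilot sample size (default 200000).
#' @param tol calibration tolerance on the realized pilot Spearman
#'   correlation (default 0.002).
#' @return named numeric vector of latent correlations, with the achieved
#'   pilot correlations in `attr(, "achieved")`.
#' @export
calibrate_copula <- function(targets, margins, survival_rho = 0.93,
                             n_pilot = 2e5, tol = 0.002) {
  stopifnot(!is.null(names(targets)), all(names(targets) %in% names(margins)),
            survival_rho > 0, survival_rho <= 1)
  z0 <- rnorm(n_pilot)
  eps <- rnorm(n_pilot)
  zt <- survival_rho * z0 + sqrt(1 - survival_rho^2) * rnorm(n_pilot)
  r0 <- rank(zt)  # survival time is monotone in its latent
  rho <- achieved <- setNames(numeric(length(targets)), names(targets))
  for (nm in names(targets)) {
    tgt <- targets[[nm]]
    if (abs(tgt) >= 1)
      stop("calibrate_copula: |target| must be < 1 for '", nm, "'")
    if (tgt == 0) next
    cuts <- qnorm(cumsum(margins[[nm]]))
    cuts <- cuts[is.finite(cuts)]
    realized <- function(r) {
      x <- findInterval(r * z0 + sqrt(1 - r^2) * eps, cuts)
      cor(rank(x), r0)
    }
    s <- sign(tgt)
    bound <- realized(0.9999)
    if (abs(tgt) > bound - tol)
      stop("calibrate_copula: target ", sprintf("%+.3f", tgt), " for '", nm,
           "' exceeds the attainable Spearman bound ", sprintf("%.3f", s * bound),
           " for its ordinal margins")
    lo <- 0; hi <- 0.9999
    for (iter in 1:40) {
      mid <- (lo + hi) / 2
      val <- realized(mid)
      if (abs(val - abs(tgt)) < tol) { lo <- hi <- mid; break }
      if (val < abs(tgt)) lo <- mid else hi <- mid
    }
    rho[nm] <- s * (lo + hi) / 2
    achieved[nm] <- s * realized((lo + hi) / 2)
  }
  attr(rho, "achieved") <- achieved
  rho
}

#' Generate a synthetic patient cohort
#'
#' Draws a cohort from the one-factor Gaussian copula described in
#' [simulation_config()]: latent prognosis factor
#' \eqn{Z_0 \sim N(0, 1)}, per-variable latents
#' \eqn{Z_j = \rho_j Z_0 + \sqrt{1-\rho_j^2}\,\varepsilon_j} discretized at
#' the marginal-probability thresholds, survival latent
#' \eqn{Z_T = \rho_T Z_0 + \sqrt{1-\rho_T^2}\,\varepsilon_T} transformed to
#' an exponential survival time \eqn{T = F^{-1}_{\mathrm{Exp}}(\Phi(Z_T))},
#' and administrative censoring at the configured window.  Deterministic
#' given `config$seed`.
#'
#' @param config a [simulation_config()] object.
#' @return a [as_cohort()] object; the (possibly lazily calibrated) config
#'   is attached as `attr(, "config")`.
#' @examples
#' coh <- generate_cohort(simulation_config(n = 63, seed = 1))
#' print(coh)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(config$latent_rho))
    config$latent_rho <- calibrate_copula(config$targets, config$margins,
                                          config$survival_rho)
  rho <- config$latent_rho[names(config$specs)]
  rho[is.na(rho)] <- 0
  if (any(abs(rho) >= 1))
    stop("generate_cohort: infeasible latent correlation (|rho| >= 1) for: ",
         paste(names(rho)[abs(rho) >= 1], collapse = ", "))

  n <- config$n
  z0 <- rnorm(n)
  data <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                     stringsAsFactors = FALSE)
  rt <- config$survival_rho
  zt <- rt * z0 + sqrt(1 - rt^2) * rnorm(n)
  t_true <- qexp(pnorm(zt), rate = log(2) / config$median_survival)
  t_true <- pmax(t_true, .Machine$double.eps)
  event <- as.integer(t_true <= config$censor_window)
  data$survival_time <- pmin(t_true, config$censor_window)
  data$event <- event
  for (nm in names(config$specs)) {
    r <- rho[[nm]]
    z <- r * z0 + sqrt(1 - r^2) * rnorm(n)
    cuts <- qnorm(cumsum(config$margins[[nm]]))
    cuts <- cuts[seq_len(length(cuts) - 1L)]
    data[[nm]] <- config$specs[[nm]]$values[findInterval(z, cuts) + 1L]
  }
  out <- as_cohort(data, config$specs)
  attr(out, "config") <- config
  out
}
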