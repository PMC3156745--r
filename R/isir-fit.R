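#' Screen candidate variables against survival
#'
#' Each candidate is correlated with the observed survival time
#' ([spearman_survival()]; the censoring flag is ignored at this stage) and
#' labelled by the sign of any significant correlation: `aggressive`
#' (negative correlation, shorter survival with higher values),
#' `protective` (positive), or `excluded` (not significant at `alpha`).
#' A candidate that is constant in the cohort has an undefined correlation
#' and is recorded as `excluded` with `r_s = NA`.
#' For the descriptive screening table the per-variable log-rank test across
#' the variable's realized levels and the univariate AUC for separating
#' <=12-month from >=60-month survivors (variable oriented so that higher
#' means higher risk) are also reported, mirroring the usual univariate
#' screening summary.
#'
#' @param cohort a [as_cohort()] object.
#' @param candidates character vector of variable names (default: all
#'   declared variables).
#' @param alpha two-sided significance level for the Spearman screen
#'   (default 0.05).
#' @param require_score error (rather than return) when no protective
#'   variable is significant, i.e. when the ISIR denominator would be empty
#'   (default `TRUE`, the behaviour [fit_isir()] relies on).
#' @param descriptive add log-rank and univariate-AUC columns (default
#'   `TRUE`; the fitting path switches it off).
#' @return a data.frame of class `isir_screen` with columns `variable`, `n`,
#'   `r_s`, `p_value`, `role`, and (if `descriptive`) `logrank_chisq`,
#'   `logrank_df`, `logrank_p`, `auc`.
#' @export
screen_variables <- function(cohort, candidates = names(cohort$specs),
                             alpha = 0.05, require_score = TRUE,
                             descriptive = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  if (!length(candidates)) stop("screen_variables: no candidate variables")
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1))
    stop("screen_variables: alpha must be in (0, 1)")
  cm <- cohort_matrix(cohort, candidates)
  scr <- screen_impl(cm$X, cm$time, alpha)
  if (descriptive) {
    grp <- assign_survival_group(cm$time, cm$event)
    extra <- lapply(seq_along(candidates), function(j) {
      x <- cm$X[, j]
      lr <- tryCatch(logrank_test(cm$time, cm$event, x, candidates[j]),
                     error = function(e) NULL)
      oriented <- if (!is.na(scr$r_s[j]) && scr$r_s[j] > 0) -x else x  # higher = higher risk
      auc <- tryCatch(roc_auc(oriented, grp)$auc, error = function(e) NA_real_)
      c(if (is.null(lr)) c(NA_real_, NA_real_, NA_real_)
        else c(lr$statistic, lr$df, lr$p_value), auc)
    })
    extra <- do.call(rbind, extra)
    scr$logrank_chisq <- extra[, 1]
    scr$logrank_df <- extra[, 2]
    scr$logrank_p <- extra[, 3]
    scr$auc <- extra[, 4]
  }
  if (require_score && !any(scr$role == "protective"))
    stop("ISIR score undefined: no candidate has a significant positive ",
         "(protective) correlation with survival at alpha = ", alpha,
         "; the score's denominator would be empty")
  attr(scr, "alpha") <- alpha
  class(scr) <- c("isir_screen", "data.frame")
  scr
}

# Internal screening on a numeric matrix: Spearman r, t-approximation p and
# role label per column.  A constant column has an undefined correlation and
# is recorded as excluded (r_s = NA) rather than aborting the screen.
# Hot path for LOO, so no cohort overhead here.
screen_impl <- function(X, time, alpha) {
  n <- length(time)
  rt <- rank(time)
  r <- apply(X, 2L, function(x) {
    if (length(unique(x)) < 2L) NA_real_ else cor(rank(x), rt)
  })
  p <- vapply(r, function(ri) if (is.na(ri)) NA_real_
              else spearman_t_pvalue(ri, n), 0)
  role <- ifelse(is.na(r), "excluded",
                 ifelse(p < alpha & r < 0, "aggressive",
                        ifelse(p < alpha & r > 0, "protective", "excluded")))
  data.frame(variable = colnames(X), n = n, r_s = r, p_value = p,
             role = role, row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.isir_screen <- function(x, digits = 3, ...) {
  cat(sprintf("Variable screening against survival (alpha = %g, n = %d)\n",
              attr(x, "alpha"), x$n[1]))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Fit the Integrated Score for Individual Risk (ISIR)
#'
#' Screens the candidate variables ([screen_variables()]) and retains those
#' with a significant Spearman correlation to survival.  The fitted score of
#' a patient is the ratio
#' \deqn{ISIR = \frac{\sum_i w_i \tilde x_i / \sum_i w_i}
#'                   {\sum_j v_j \tilde y_j / \sum_j v_j}}{
#'       ISIR = (sum_i w_i x~_i / sum_i w_i) / (sum_j v_j y~_j / sum_j v_j)}
#' where the \eqn{x_i} are the aggressive variables with weights
#' \eqn{w_i = |r_S(x_i, t)|}, the \eqn{y_j} the protective variables with
#' weights \eqn{v_j = r_S(y_j, t)}, and every value is scaled by its number
#' of possible realizations ([scale_value()]).  Large values indicate high
#' risk.  The weighted-average normalisation (division by the weight sums)
#' is the default; `normalize = FALSE` keeps raw weighted sums instead.
#'
#' @inheritParams screen_variables
#' @param normalize divide numerator and denominator by their weight sums
#'   (default `TRUE`).
#' @param preset risk-class cut-off preset, see [classify_risk()].
#' @param cutoff binary good/bad cut-off, see [classify_binary()].
#' @return an object of class `isir`: weights, divisors, screening table,
#'   and the fitted training scores (`$fitted`).
#' @examples
#' cfg <- simulation_config(n = 200, seed = 7)
#' coh <- generate_cohort(cfg)
#' fit <- fit_isir(coh)
#' coef(fit)
#' head(predict(fit, coh))
#' @seealso [isir_model()] to build a score from published weights,
#'   [loo_cross_validate()] for validation.
#' @export
fit_isir <- function(cohort, candidates = names(cohort$specs), alpha = 0.05,
                     normalize = TRUE, preset = "methods", cutoff = 0.5) {
  stopifnot(inherits(cohort, "cohort"))
  if (nrow(cohort$data) < 3L) stop("fit_isir: need at least 3 patients")
  scr <- screen_variables(cohort, candidates, alpha, require_score = TRUE,
                          descriptive = FALSE)
  model <- isir_from_screen(scr, cohort$specs, alpha, normalize, preset, cutoff)
  model$call <- match.call()
  model$fitted <- isir_score(model, cohort)
  model$fitted$survival_time <- cohort$data$survival_time
  model$fitted$event <- cohort$data$event
  model$fitted$survival_group <- assign_survival_group(
    cohort$data$survival_time, cohort$data$event)
  model
}

# Assemble an isir object from a screening table (internal; shared by
# fit_isir and the LOO loop).
isir_from_screen <- function(scr, specs, alpha, normalize, preset, cutoff) {
  agg <- scr[scr$role == "aggressive", , drop = FALSE]
  pro <- scr[scr$role == "protective", , drop = FALSE]
  if (!nrow(pro))
    stop("ISIR score undefined: no significant protective variable ",
         "(empty denominator)")
  if (!nrow(agg))
    warning("fit_isir: no significant aggressive variable; ",
            "all scores will be 0")
  build <- function(tab, w) data.frame(
    variable = tab$variable, weight = w, r_s = tab$r_s,
    divisor = vapply(specs[tab$variable], `[[`, 0L, "divisor"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    aggressive = build(agg, abs(agg$r_s)),
    protective = build(pro, pro$r_s),
    alpha = alpha, normalize = normalize,
    preset = preset, cutoff = cutoff,
    n = scr$n[1], screening = scr,
    specs = specs[c(agg$variable, pro$variable)]
  ), class = "isir")
}

#' Build an ISIR model from published weights
#'
#' Constructs the scoring object directly from correlation weights (e.g.
#' values reported for another cohort) without refitting, so the score can
#' be applied to new patients.
#'
#' @param aggressive named numeric vector of positive weights
#'   (\eqn{|r_S|}) for the aggressive variables.
#' @param protective named numeric vector of positive weights (\eqn{r_S})
#'   for the protective variables (at least one required).
#' @param specs named list of [variable_spec()]s covering all weighted
#'   variables (supplies the scale divisors).
#' @inheritParams fit_isir
#' @return an object of class `isir`.
#' @examples
#' w <- isir_model(aggressive = c(T = 0.55, N = 0.41, M = 0.37),
#'                 protective = c(Gas6 = 0.31, CD68 = 0.32),
#'                 specs = default_variable_specs())
#' isir_score(w, data.frame(patient_id = "p1", T = 2, N = 0, M = 0,
#'                          Gas6 = 1, CD68 = 3))
#' @export
isir_model <- function(aggressive = numeric(), protective, specs,
                       alpha = 0.05, normalize = TRUE,
                       preset = "methods", cutoff = 0.5) {
  specs <- as_spec_list(specs)
  check_w <- function(w, what) {
    if (length(w)) {
      if (is.null(names(w)) || any(!nzchar(names(w))))
        stop("isir_model: ", what, " weights must be named")
      if (any(w <= 0)) stop("isir_model: ", what, " weights must be positive")
      missing <- setdiff(names(w), names(specs))
      if (length(missing))
        stop("isir_model: no variable_spec for: ", paste(missing, collapse = ", "))
    }
  }
  check_w(aggressive, "aggressive")
  check_w(protective, "protective")
  if (!length(protective))
    stop("ISIR score undefined: at least one protective variable is required")
  build <- function(w) data.frame(
    variable = names(w), weight = unname(w), r_s = NA_real_,
    divisor = vapply(specs[names(w)], `[[`, 0L, "divisor"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    aggressive = build(aggressive), protective = build(protective),
    alpha = alpha, normalize = normalize, preset = preset, cutoff = cutoff,
    n = NA_integer_, screening = NULL,
    specs = specs[c(names(aggressive), names(protective))]
  ), class = "isir")
}

#' Score patients with a fitted ISIR model
#'
#' @param model an `isir` object ([fit_isir()] or [isir_model()]).
#' @param newdata a `cohort` or a data.frame with one column per model
#'   variable (and optionally `patient_id`).
#' @return a data.frame of class `isir_scores`: `patient_id`, `isir`,
#'   `risk_class` (low/intermediate/high per the model's preset) and
#'   `binary_class` (good/bad at the model's cut-off).
#' @export
isir_score <- function(model, newdata) {
  stopifnot(inherits(model, "isir"))
  df <- if (inherits(newdata, "cohort")) newdata$data else as.data.frame(newdata)
  vars <- c(model$aggressive$variable, model$protective$variable)
  missing <- setdiff(vars, names(df))
  if (length(missing))
    stop("isir_score: missing covariate(s): ", paste(missing, collapse = ", "))
  for (nm in vars) {
    sp <- model$specs[[nm]]
    if (!is.null(sp)) {
      bad <- !(df[[nm]] %in% sp$values)
      if (any(bad))
        stop("isir_score: inadmissible value for '", nm, "': ",
             paste(unique(df[[nm]][bad]), collapse = ", "))
    }
  }
  scores <- isir_score_matrix(model, as.matrix(df[vars]))
  out <- data.frame(
    patient_id = if ("patient_id" %in% names(df)) as.character(df$patient_id)
                 else as.character(seq_len(nrow(df))),
    isir = scores,
    risk_class = classify_risk(scores, preset = model$preset),
    binary_class = classify_binary(scores, cutoff = model$cutoff),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("isir_scores", "data.frame")
  out
}

# Internal vectorized scorer: X has columns in model order (aggressive then
# protective), raw coding.  Returns the score vector; denominator 0 -> error.
isir_score_matrix <- function(model, X) {
  ka <- nrow(model$aggressive)
  num <- if (ka) {
    Xa <- X[, seq_len(ka), drop = FALSE]
    Xa <- sweep(Xa, 2L, model$aggressive$divisor, `/`)
    s <- drop(Xa %*% model$aggressive$weight)
    if (model$normalize) s / sum(model$aggressive$weight) else s
  } else rep(0, nrow(X))
  Xp <- X[, ka + seq_len(nrow(model$protective)), drop = FALSE]
  Xp <- sweep(Xp, 2L, model$protective$divisor, `/`)
  den <- drop(Xp %*% model$protective$weight)
  if (model$normalize) den <- den / sum(model$protective$weight)
  if (any(den <= 0))
    stop("ISIR score undefined for patient(s) ",
         paste(which(den <= 0), collapse = ", "),
         ": all protective scaled values are zero (denominator 0)")
  num / den
}

#' Assign three-level risk classes to ISIR scores
#'
#' Two printed presets are supported.  The default `"methods"` preset uses
#' inclusive outer bands: score <= 0.25 is low risk, >= 0.5 high risk,
#' anything strictly between is intermediate.  The `"table3"` preset uses
#' strict outer bands < 0.4 (low) and > 0.8 (high), boundaries falling to
#' intermediate.  A custom numeric pair `c(low, high)` behaves like
#' `"table3"` (strict outer bands).
#'
#' @param score non-negative score(s).
#' @param preset `"methods"`, `"table3"`, or a numeric `c(low, high)` pair.
#' @return factor with levels `low`, `intermediate`, `high`.
#' @export
classify_risk <- function(score, preset = "methods") {
  if (any(!is.finite(score)) || any(score < 0))
    stop("classify_risk: scores must be non-negative")
  if (is.character(preset)) {
    preset <- match.arg(preset, c("methods", "table3"))
    lab <- if (preset == "methods") {
      ifelse(score <= 0.25, "low", ifelse(score >= 0.5, "high", "intermediate"))
    } else {
      ifelse(score < 0.4, "low", ifelse(score > 0.8, "high", "intermediate"))
    }
  } else {
    stopifnot(is.numeric(preset), length(preset) == 2L, preset[1] < preset[2])
    lab <- ifelse(score < preset[1], "low",
                  ifelse(score > preset[2], "high", "intermediate"))
  }
  factor(lab, levels = c("low", "intermediate", "high"))
}

#' Binary good/bad classification of a risk score
#'
#' `good` if the score is at or below the cut-off (default 0.5), `bad`
#' above it; a score exactly at the cut-off is good.
#'
#' @param score non-negative score(s).
#' @param cutoff scalar cut-off (default 0.5).
#' @return factor with levels `good`, `bad`.
#' @export
classify_binary <- function(score, cutoff = 0.5) {
  if (any(!is.finite(score)) || any(score < 0))
    stop("classify_binary: scores must be non-negative")
  factor(ifelse(score <= cutoff, "good", "bad"), levels = c("good", "bad"))
}

#' @export
print.isir <- function(x, digits = 3, ...) {
  cat("Integrated Score for Individual Risk (ISIR)\n")
  if (!is.na(x$n)) cat(sprintf("  fitted on %d patients, alpha = %g\n", x$n, x$alpha))
  fmt <- function(tab) paste(sprintf("%s (%.*f)", tab$variable, digits, tab$weight),
                             collapse = ", ")
  cat("  aggressive (numerator):",
      if (nrow(x$aggressive)) fmt(x$aggressive) else "none", "\n")
  cat("  protective (denominator):", fmt(x$protective), "\n")
  cat(sprintf("  risk classes: preset '%s'; binary cut-off %.2f (good <= cutoff)\n",
              if (is.character(x$preset)) x$preset else
                paste(x$preset, collapse = "/"), x$cutoff))
  invisible(x)
}

#' @export
coef.isir <- function(object, ...) {
  c(setNames(-object$aggressive$weight, object$aggressive$variable),
    setNames(object$protective$weight, object$protective$variable))
}

#' @export
predict.isir <- function(object, newdata, type = c("score", "class", "binary"), ...) {
  type <- match.arg(type)
  sc <- isir_score(object, newdata)
  switch(type,
         score = sc,
         class = sc$risk_class,
         binary = sc$binary_class)
}

#' @export
summary.isir <- function(object, ...) {
  out <- list(model = object)
  if (!is.null(object$fitted) && !is.null(object$fitted$survival_group)) {
    f <- object$fitted
    grp <- f$survival_group
    out$n <- nrow(f)
    out$table3 <- classification_table(f$risk_class, grp)
    out$binary <- classification_table(f$binary_class, grp)
    out$accuracy <- tryCatch(pooled_accuracy(out$binary), error = function(e) NULL)
    out$roc <- tryCatch(roc_auc(f$isir, grp), error = function(e) NULL)
  }
  class(out) <- "summary.isir"
  out
}

#' @export
print.summary.isir <- function(x, ...) {
  print(x$model)
  if (!is.null(x$model$screening)) {
    cat("\nScreening:\n")
    print.data.frame(x$model$screening, digits = 3, row.names = FALSE)
  }
  if (!is.null(x$binary)) {
    cat("\nTraining-set classification (binary vs survival groups):\n")
    print(x$binary)
    if (!is.null(x$roc))
      cat(sprintf("\nTraining-set AUC (<=12 vs >=60 months): %.3f\n", x$roc$auc))
    if (!is.null(x$accuracy))
      cat(sprintf("Pooled accuracy among clear-prognosis patients: %d/%d (%.0f%%)\n",
                  x$accuracy$correct, x$accuracy$n, x$accuracy$percent))
  }
  invisible(x)
}

#' Plot a fitted ISIR model
#'
#' Scatter plot of the fitted scores against observed survival time, with
#' censored patients marked and the risk-class cut-offs drawn, the usual
#' visual check that large scores go with short survival.
#'
#' @param x a fitted `isir` object (from [fit_isir()], so `$fitted` exists).
#' @param ... passed to [graphics::plot()].
#' @export
plot.isir <- function(x, ...) {
  if (is.null(x$fitted) || is.null(x$fitted$survival_time))
    stop("plot.isir: model carries no fitted training scores")
  f <- x$fitted
  graphics::plot(f$isir, f$survival_time,
                 pch = ifelse(f$event == 1, 19, 1),
                 xlab = "ISIR", ylab = "survival time (months)", ...)
  graphics::abline(v = x$cutoff, lty = 2)
  graphics::abline(h = c(12, 60), lty = 3, col = "grey50")
  graphics::legend("topright", pch = c(19, 1), bty = "n",
                   legend = c("death observed", "censored"))
  invisible(x)
}
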