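#' Cox proportional-hazards comparator with backward elimination
#'
#' Fits the proportional-hazards model
#' \eqn{\lambda(t, X) = \lambda_0(t) \exp(X\beta)} by partial likelihood
#' ([survival::coxph()], Breslow tie handling by default, matching the SAS
#' PHREG convention) on the original ordinal coding, then performs automatic
#' backward elimination: while any retained variable's Wald p-value exceeds
#' `p_remove`, the variable with the largest p-value is dropped (ties broken
#' by candidate-list order) and the model refitted.  The baseline hazard is
#' never estimated; patients are ranked and classified by the raw linear
#' predictor \eqn{X \beta} alone.
#'
#' @inheritParams fit_isir
#' @param p_remove removal threshold for the Wald p-value (default 0.05).
#' @param ties tie-handling method passed to [survival::coxph()]
#'   (`"breslow"` default, `"efron"` available).
#' @return an object of class `cox_backward`: `coefficients` (named, on the
#'   original unscaled coding; length 0 if everything was eliminated),
#'   `trace` (data.frame of removed variables with the p-value at removal),
#'   `fit` (the final [survival::coxph()] object, or `NULL` for the empty
#'   model), `n`, `n_event`.
#' @examples
#' coh <- generate_cohort(simulation_config(n = 200, seed = 3))
#' cx <- fit_cox_backward(coh)
#' coef(cx)
#' @export
fit_cox_backward <- function(cohort, candidates = names(cohort$specs),
                             p_remove = 0.05, ties = c("breslow", "efron")) {
  stopifnot(inherits(cohort, "cohort"))
  ties <- match.arg(ties)
  cm <- cohort_matrix(cohort, candidates)
  if (sum(cm$event) < 2L) stop("fit_cox_backward: need at least 2 events")
  constant <- candidates[apply(cm$X, 2L, function(x) length(unique(x)) < 2L)]
  if (length(constant))
    stop("fit_cox_backward: constant candidate variable(s): ",
         paste(constant, collapse = ", "))

  dat <- as.data.frame(cm$X)
  dat$.time <- cm$time
  dat$.event <- cm$event
  current <- candidates
  trace <- data.frame(step = integer(), variable = character(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  fit <- NULL
  while (length(current)) {
    fml <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~",
      paste(sprintf("`%s`", current), collapse = " + ")))
    fit <- survival::coxph(fml, data = dat, ties = ties)
    beta <- coef(fit)
    names(beta) <- current
    if (any(!is.finite(beta)) || any(abs(beta) > 15))
      stop("fit_cox_backward: partial likelihood did not converge ",
           "(monotone likelihood / separation) for variable(s): ",
           paste(current[!is.finite(beta) | abs(beta) > 15], collapse = ", "))
    se <- sqrt(diag(fit$var))
    p <- 2 * pnorm(-abs(beta / se))
    if (max(p) <= p_remove) break
    drop_j <- which(p == max(p))[1L]  # tie -> earliest in candidate order
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, variable = current[drop_j],
                                     p_value = p[drop_j],
                                     stringsAsFactors = FALSE))
    current <- current[-drop_j]
    fit <- NULL
  }

  coefs <- if (length(current)) setNames(as.numeric(coef(fit)), current)
           else setNames(numeric(0), character(0))
  structure(list(coefficients = coefs, trace = trace, fit = fit,
                 variables = current, p_remove = p_remove, ties = ties,
                 n = nrow(dat), n_event = sum(cm$event),
                 call = match.call()),
            class = "cox_backward")
}

#' @export
print.cox_backward <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional-hazards model (backward elimination at p > %g, %s ties)\n",
              x$p_remove, x$ties))
  cat(sprintf("  n = %d patients, %d events\n", x$n, x$n_event))
  if (length(x$coefficients)) {
    cat("  retained coefficients:\n")
    print(round(x$coefficients, digits))
  } else {
    cat("  no variable retained (empty model)\n")
  }
  if (nrow(x$trace)) {
    cat("  removed: ",
        paste(sprintf("%s (p=%.3f)", x$trace$variable, x$trace$p_value),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.cox_backward <- function(object, ...) object$coefficients

#' @export
summary.cox_backward <- function(object, ...) {
  if (is.null(object$fit)) {
    print(object)
    return(invisible(object))
  }
  summary(object$fit)
}

#' Linear-predictor risk score from a Cox model
#'
#' The score of a patient is the raw linear predictor
#' \eqn{\sum_k \beta_k x_k} on the original (unscaled) covariate coding;
#' large values indicate short predicted survival.
#'
#' @param model a `cox_backward` object, or a named coefficient vector.
#' @param newdata a `cohort` or data.frame carrying all model variables.
#' @return data.frame with `patient_id` and `score`.
#' @export
cox_score <- function(model, newdata) {
  beta <- if (inherits(model, "cox_backward")) model$coefficients
          else { stopifnot(is.numeric(model), !is.null(names(model))); model }
  df <- if (inherits(newdata, "cohort")) newdata$data else as.data.frame(newdata)
  missing <- setdiff(names(beta), names(df))
  if (length(missing))
    stop("cox_score: missing covariate(s): ", paste(missing, collapse = ", "))
  score <- if (length(beta))
    drop(as.matrix(df[names(beta)]) %*% beta)
  else rep(0, nrow(df))
  data.frame(
    patient_id = if ("patient_id" %in% names(df)) as.character(df$patient_id)
                 else as.character(seq_len(nrow(df))),
    score = score, row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
predict.cox_backward <- function(object, newdata, ...) cox_score(object, newdata)

#' Risk classes for the Cox linear-predictor score
#'
#' Binary classification splits at a cut-off of -5.5 (scores at or below it
#' are `good`, above it `bad`).  The three-class preset uses strict outer
#' bands: score < -6 is low risk, > -4.5 high risk, boundaries and the band
#' between falling to intermediate.
#'
#' @param score numeric linear-predictor score(s).
#' @param type `"binary"` or `"three_class"`.
#' @param cutoff binary cut-off (default -5.5).
#' @param bands three-class band `c(low, high)` (default `c(-6, -4.5)`).
#' @return factor: `good`/`bad` or `low`/`intermediate`/`high`.
#' @export
classify_cox <- function(score, type = c("binary", "three_class"),
                         cutoff = -5.5, bands = c(-6, -4.5)) {
  type <- match.arg(type)
  if (any(!is.finite(score))) stop("classify_cox: scores must be finite")
  if (type == "binary")
    return(factor(ifelse(score <= cutoff, "good", "bad"),
                  levels = c("good", "bad")))
  stopifnot(length(bands) == 2L, bands[1] < bands[2])
  factor(ifelse(score < bands[1], "low",
                ifelse(score > bands[2], "high", "intermediate")),
         levels = c("low", "intermediate", "high"))
}
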