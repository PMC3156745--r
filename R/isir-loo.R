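#' Leave-one-out cross-validation of the ISIR score
#'
#' For each patient the entire fitting pipeline is repeated on the other
#' \eqn{n - 1} patients -- re-screening the candidates and re-deriving the
#' correlation weights -- and the held-out patient is scored and classified
#' by that fold's model, so variable selection uncertainty is reflected in
#' the validation (mode `"refit"`, the default).  Mode `"weights-fixed"`
#' instead fits once on the full cohort and scores every patient with that
#' fixed model (the resubstitution comparison).  Folds whose model is
#' undefined (no significant protective variable among the remaining
#' patients) are recorded as unclassifiable, never silently dropped.
#'
#' @inheritParams fit_isir
#' @param mode `"refit"` (re-screen and re-weight per fold) or
#'   `"weights-fixed"`.
#' @return an object of class `isir_loo`: per-patient data.frame `folds`
#'   (`patient_id`, `isir`, `risk_class`, `binary_class`, `survival_group`,
#'   `classifiable`), the binary classification `table`, `accuracy`
#'   ([pooled_accuracy()] among classifiable le12/ge60 patients, or `NULL`
#'   when none), and `n_unclassifiable`.
#' @examples
#' coh <- generate_cohort(simulation_config(n = 63, seed = 11))
#' cv <- loo_cross_validate(coh)
#' cv$accuracy
#' @export
loo_cross_validate <- function(cohort, candidates = names(cohort$specs),
                               alpha = 0.05, cutoff = 0.5,
                               preset = "methods",
                               mode = c("refit", "weights-fixed"),
                               normalize = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  mode <- match.arg(mode)
  n <- nrow(cohort$data)
  if (n < 4L) stop("loo_cross_validate: need at least 4 patients")
  cm <- cohort_matrix(cohort, candidates)

  score_one <- function(model, i) {
    vars <- c(model$aggressive$variable, model$protective$variable)
    isir_score_matrix(model, cm$X[i, match(vars, candidates), drop = FALSE])
  }

  scores <- rep(NA_real_, n)
  if (mode == "weights-fixed") {
    model <- fit_isir(cohort, candidates, alpha, normalize, preset, cutoff)
    scores <- score_one(model, seq_len(n))
  } else {
    for (i in seq_len(n)) {
      scr <- screen_impl(cm$X[-i, , drop = FALSE], cm$time[-i], alpha)
      model <- tryCatch(
        suppressWarnings(isir_from_screen(scr, cohort$specs, alpha,
                                          normalize, preset, cutoff)),
        error = function(e) NULL)
      if (!is.null(model))
        scores[i] <- tryCatch(score_one(model, i), error = function(e) NA_real_)
    }
  }

  ok <- !is.na(scores)
  folds <- data.frame(
    patient_id = cm$id,
    isir = scores,
    risk_class = factor(NA, levels = c("low", "intermediate", "high")),
    binary_class = factor(NA, levels = c("good", "bad")),
    survival_group = assign_survival_group(cm$time, cm$event),
    classifiable = ok,
    row.names = NULL, stringsAsFactors = FALSE)
  if (any(ok)) {
    folds$risk_class[ok] <- classify_risk(scores[ok], preset)
    folds$binary_class[ok] <- classify_binary(scores[ok], cutoff)
  }

  tab <- if (any(ok))
    classification_table(folds$binary_class[ok], folds$survival_group[ok])
  else NULL
  acc <- if (!is.null(tab))
    tryCatch(pooled_accuracy(tab), error = function(e) NULL)
  else NULL

  structure(list(folds = folds, table = tab, accuracy = acc,
                 n = n, n_unclassifiable = sum(!ok),
                 mode = mode, alpha = alpha, cutoff = cutoff),
            class = "isir_loo")
}

#' @export
print.isir_loo <- function(x, ...) {
  cat(sprintf("Leave-one-out cross-validation of ISIR (%s mode), n = %d\n",
              x$mode, x$n))
  if (x$n_unclassifiable > 0)
    cat(sprintf("  %d fold(s) unclassifiable (no significant protective variable)\n",
                x$n_unclassifiable))
  if (!is.null(x$table)) {
    cat("Held-out binary classification vs survival groups:\n")
    print(x$table)
  }
  if (!is.null(x$accuracy)) print(x$accuracy)
  invisible(x)
}
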