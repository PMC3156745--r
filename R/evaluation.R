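#' ROC curve and AUC for short- versus long-survivor discrimination
#'
#' Evaluates how well a risk score separates patients who survived at most
#' 12 months (positives) from those who survived at least 60 months
#' (negatives); patients in the ambiguous 12--60-month group are excluded
#' before computation.  The AUC is the Mann-Whitney pairwise-comparison
#' probability that a positive outscores a negative, with half credit for
#' ties.  Thresholds run over all distinct observed scores plus infinite
#' endpoints; a patient is called positive when their score is at or above
#' the threshold.
#'
#' @param scores numeric risk scores (higher = higher predicted risk).
#' @param groups survival-group labels as produced by
#'   [assign_survival_group()] (`le12`/`mid`/`ge60`).
#' @return an object of class `isir_roc`: data.frame `curve` (`threshold`,
#'   `tpr`, `fpr`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, groups) {
  if (length(scores) != length(groups))
    stop("roc_auc: scores and groups must have the same length")
  groups <- factor(groups, levels = c("le12", "mid", "ge60"))
  if (anyNA(groups)) stop("roc_auc: unknown survival-group label")
  keep <- groups != "mid"
  s <- scores[keep]
  pos <- groups[keep] == "le12"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("roc_auc: need at least one patient in each of the le12 and ge60 groups")
  # Mann-Whitney via mid-ranks: ties between a positive and a negative
  # contribute exactly 1/2.
  r <- rank(s)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  tpr <- vapply(th, function(t) mean(s[pos] >= t), 0)
  fpr <- vapply(th, function(t) mean(s[!pos] >= t), 0)
  structure(list(curve = data.frame(threshold = th, tpr = tpr, fpr = fpr),
                 auc = auc, n_pos = n1, n_neg = n0),
            class = "isir_roc")
}

#' @export
print.isir_roc <- function(x, ...) {
  cat(sprintf("ROC for <=12-month (n=%d) vs >=60-month (n=%d) survivors: AUC = %.3f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' @export
plot.isir_roc <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$tpr, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", x$auc))
  invisible(x)
}

#' Cross-tabulate risk classes against survival groups
#'
#' Builds the risk-class-by-survival-group contingency table used to report
#' a score's prognostic performance.  For binary (good/bad) predictions the
#' table also carries sensitivity (correctly predicted `bad` among
#' <=12-month survivors) and specificity (correctly predicted `good` among
#' >=60-month survivors), reported as numerator/denominator fractions in the
#' print method.
#'
#' @param predictions risk-class labels: levels `low`/`intermediate`/`high`
#'   or `good`/`bad` (a factor, or a character vector using one of those
#'   label sets).
#' @param groups survival-group labels (`le12`/`mid`/`ge60`).
#' @return an object of class `risk_table`: `counts` (matrix with margins),
#'   and for binary predictions `sensitivity`/`specificity` as
#'   `c(numerator, denominator)`.
#' @export
classification_table <- function(predictions, groups) {
  if (!length(predictions) || length(predictions) != length(groups))
    stop("classification_table: predictions and groups must be non-empty and equal length")
  groups <- factor(groups, levels = c("le12", "mid", "ge60"))
  if (anyNA(groups)) stop("classification_table: unknown survival-group label")
  if (!is.factor(predictions)) {
    u <- unique(as.character(predictions))
    lev <- if (all(u %in% c("good", "bad"))) c("good", "bad")
           else c("low", "intermediate", "high")
    predictions <- factor(as.character(predictions), levels = lev)
  }
  if (anyNA(predictions))
    stop("classification_table: unknown risk-class label")
  counts <- table(prediction = predictions, group = groups)
  out <- list(counts = unclass(counts),
              row_totals = rowSums(counts), col_totals = colSums(counts),
              n = sum(counts))
  if (identical(levels(predictions), c("good", "bad"))) {
    out$sensitivity <- c(counts["bad", "le12"], sum(counts[, "le12"]))
    out$specificity <- c(counts["good", "ge60"], sum(counts[, "ge60"]))
  }
  class(out) <- "risk_table"
  out
}

#' @export
print.risk_table <- function(x, ...) {
  m <- cbind(x$counts, total = x$row_totals)
  m <- rbind(m, total = c(x$col_totals, x$n))
  print(m)
  frac <- function(v) sprintf("%d/%d%s", v[1], v[2],
                              if (v[2] > 0) sprintf(" (%.0f%%)", 100 * v[1] / v[2]) else "")
  if (!is.null(x$sensitivity))
    cat("sensitivity (bad | le12):", frac(x$sensitivity),
        "  specificity (good | ge60):", frac(x$specificity), "\n")
  invisible(x)
}

#' Pooled accuracy among clear-prognosis patients
#'
#' The headline figure for a binary risk classification: the proportion of
#' correctly classified patients among those with an unambiguous outcome
#' (`bad` predictions among <=12-month survivors plus `good` predictions
#' among >=60-month survivors, over all patients in those two groups).
#' Patients in the 12--60-month group do not enter the denominator.
#'
#' @param table a binary [classification_table()] (`good`/`bad` rows), or a
#'   2-by-k count matrix with rows `good`,`bad` and columns including
#'   `le12`,`ge60`.
#' @return a list of class `pooled_accuracy`: `correct`, `n`, `proportion`,
#'   and `percent` (rounded to the nearest integer).
#' @examples
#' m <- matrix(c(2, 19, 12, 5), 2, dimnames = list(c("good", "bad"),
#'                                                 c("le12", "ge60")))
#' pooled_accuracy(m)  # 31/38, 82%
#' @export
pooled_accuracy <- function(table) {
  counts <- if (inherits(table, "risk_table")) table$counts else as.matrix(table)
  if (is.null(rownames(counts)) || !all(c("good", "bad") %in% rownames(counts)))
    stop("pooled_accuracy: need a binary (good/bad) classification table")
  if (is.null(colnames(counts)) || !all(c("le12", "ge60") %in% colnames(counts)))
    stop("pooled_accuracy: need le12 and ge60 columns")
  n <- sum(counts[, c("le12", "ge60")])
  if (n == 0L) stop("pooled_accuracy: no patients in the le12/ge60 groups")
  correct <- counts["bad", "le12"] + counts["good", "ge60"]
  structure(list(correct = as.integer(correct), n = as.integer(n),
                 proportion = correct / n,
                 percent = round(100 * correct / n)),
            class = "pooled_accuracy")
}

#' @export
print.pooled_accuracy <- function(x, ...) {
  cat(sprintf("Pooled accuracy among clear-prognosis patients: %d/%d = %.1f%% (~%d%%)\n",
              x$correct, x$n, 100 * x$proportion, x$percent))
  invisible(x)
}
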