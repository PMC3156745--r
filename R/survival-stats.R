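#' Spearman rank correlation between an ordinal variable and survival time
#'
#' Computes the tie-corrected Spearman coefficient as the Pearson correlation
#' of mid-ranks (average ranks across ties), the appropriate form for heavily
#' tied ordinal gradings.  The two-sided p-value uses the t approximation
#' \deqn{t^* = r_s \sqrt{(n-2)/(1-r_s^2)}}{t* = r_s sqrt((n-2)/(1-r_s^2))}
#' on \eqn{n - 2} degrees of freedom; for tiny samples (\eqn{n \le 8}) an
#' exact permutation p-value over all \eqn{n!} orderings is available.
#' Censoring status is deliberately not an argument: the screening stage
#' correlates covariates with the observed follow-up time, ignoring the
#' censoring flag.
#'
#' @param x integer/numeric vector of covariate values (not constant).
#' @param t vector of survival times, same length as `x` (not constant).
#' @param variable optional variable name carried into the result.
#' @param p_method `"t"` (default) or `"exact"` (full permutation
#'   enumeration, only for `n <= 8`).
#' @return a list of class `spearman_result`: `variable`, `r_s`, `p_value`,
#'   `n`, `method`.
#' @examples
#' spearman_survival(c(1, 1, 2), c(1, 2, 3))$r_s  # 0.866 on mid-ranks
#' @export
spearman_survival <- function(x, t, variable = NA_character_, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  if (length(x) != length(t))
    stop("spearman_survival: x and t must have the same length")
  n <- length(x)
  if (n < 3L) stop("spearman_survival: need at least 3 observations")
  if (anyNA(x) || anyNA(t)) stop("spearman_survival: missing values not allowed")
  if (length(unique(x)) < 2L)
    stop("spearman_survival: undefined correlation, x is constant",
         if (!is.na(variable)) paste0(" (variable '", variable, "')") else "")
  if (length(unique(t)) < 2L)
    stop("spearman_survival: undefined correlation, t is constant")

  rx <- rank(x)
  rt <- rank(t)
  r <- as.numeric(cor(rx, rt))

  if (p_method == "exact") {
    if (n > 8L)
      stop("spearman_survival: exact permutation p-value supported for n <= 8; ",
           "use p_method = 't'")
    p <- spearman_perm_pvalue(rx, rt, r)
  } else {
    p <- spearman_t_pvalue(r, n)
  }
  structure(list(variable = variable, r_s = r, p_value = p, n = n,
                 method = p_method),
            class = "spearman_result")
}

# Two-sided p from the t approximation; |r| = 1 degenerates to p = 0.
spearman_t_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tstar <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tstar), df = n - 2)
}

# Exact two-sided permutation p-value: proportion of the n! permutations of
# one rank vector whose mid-rank correlation is at least as extreme.
spearman_perm_pvalue <- function(rx, rt, r_obs) {
  perms <- permutations_of(length(rt))
  rs <- apply(perms, 1L, function(idx) cor(rx, rt[idx]))
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

# All permutations of 1..n as a matrix (n! rows); n is capped upstream.
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("Spearman rank correlation%s: r_s = %.3f, p = %.4g (n = %d, %s)\n",
              if (is.na(x$variable)) "" else paste0(" [", x$variable, "]"),
              x$r_s, x$p_value, x$n,
              if (x$method == "t") "t approximation" else "exact permutation"),
      ...)
  invisible(x)
}

#' Kaplan-Meier product-limit survival curve
#'
#' Thin wrapper around [survival::survfit()] returning the product-limit
#' estimate as a plain data.frame.  Censored observations leave the risk set
#' after their time without contributing an event.
#'
#' @param times positive survival/follow-up times.
#' @param events 0/1 event indicators (1 = death observed).
#' @return a data.frame of class `km_curve` with one row per distinct
#'   observed time: `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
kaplan_meier <- function(times, events) {
  if (!length(times)) stop("kaplan_meier: empty input")
  if (length(times) != length(events))
    stop("kaplan_meier: times and events must have the same length")
  if (any(!is.finite(times)) || any(times <= 0))
    stop("kaplan_meier: times must be positive")
  if (!all(events %in% c(0, 1))) stop("kaplan_meier: events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' K-group log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square over the pooled
#' distinct event times (hypergeometric variance, multi-death handling for
#' tied event times), via [survival::survdiff()].
#'
#' @param times positive survival/follow-up times.
#' @param events 0/1 event indicators.
#' @param group group labels (K >= 2 non-empty groups).
#' @param variable optional variable name carried into the result.
#' @return a list of class `logrank_result`: `variable`, `statistic`, `df`
#'   (`K - 1`), `p_value`.
#' @export
logrank_test <- function(times, events, group, variable = NA_character_) {
  if (length(times) != length(events) || length(times) != length(group))
    stop("logrank_test: times, events and group must have the same length")
  g <- factor(group)
  counts <- table(g)
  if (length(counts) < 2L)
    stop("logrank_test: need at least two groups")
  if (any(counts == 0L))
    stop("logrank_test: empty group(s): ",
         paste(names(counts)[counts == 0L], collapse = ", "))
  if (sum(events == 1) == 0L)
    stop("logrank_test: no events observed in any group")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- length(counts) - 1L
  structure(list(variable = variable,
                 statistic = as.numeric(sd$chisq),
                 df = df,
                 p_value = pchisq(as.numeric(sd$chisq), df, lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test%s: chi-square = %.3f on %d df, p = %.4g\n",
              if (is.na(x$variable)) "" else paste0(" [", x$variable, "]"),
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Assign patients to prognosis groups by observed survival
#'
#' Three groups anchor the evaluation of any risk score: patients surviving
#' at most 12 months (`"le12"`, poor outcome), at least 60 months (`"ge60"`,
#' favourable outcome), and the prognostically ambiguous remainder (`"mid"`).
#' Boundary times go to the outer groups (12 to `"le12"`, 60 to `"ge60"`).
#' Censored patients are assigned by their observed follow-up time: a patient
#' censored at or beyond 60 months has demonstrably survived 60 months, while
#' one censored earlier only contributes its observed lower bound (the event
#' flag is accepted so callers can audit that choice per patient).
#'
#' @param time positive observed time(s), months.
#' @param event 0/1 event indicator(s) (same length; used for auditing only).
#' @return factor with levels `le12`, `mid`, `ge60`.
#' @export
assign_survival_group <- function(time, event = rep(1L, length(time))) {
  if (any(!is.finite(time)) || any(time <= 0))
    stop("assign_survival_group: time must be positive")
  if (length(event) != length(time))
    stop("assign_survival_group: time and event must have the same length")
  lab <- ifelse(time <= 12, "le12", ifelse(time >= 60, "ge60", "mid"))
  factor(lab, levels = c("le12", "mid", "ge60"))
}
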