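---
title: "Correlation-weighted risk scoring: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-weighted risk scoring: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(isir)
```

## The problem

Prognosis in non-small cell lung cancer (and solid tumours generally) is
usually anchored on the TNM staging triple, but immunohistochemical markers
of the tumour--host interaction (e.g. macrophage infiltration measured by
CD68, Gas6 expression) carry additional information.  Each such variable is
ordinal — staging categories, or staining grades 1--4 — and no single one
discriminates well on its own.  The package implements a deliberately
simple, transparent way of condensing them into one number per patient, the
Integrated Score for Individual Risk (ISIR), together with the screening,
validation and comparator machinery around it.

## The score

**Screening.** Every candidate variable is correlated with observed
survival time using the Spearman rank correlation on mid-ranks (average
ranks across ties — the appropriate estimator for ordinal gradings with
many ties).  Two-sided p-values use the t approximation
$t^\* = r_s\sqrt{(n-2)/(1-r_s^2)}$ on $n-2$ degrees of freedom.  Variables
with a significant ($p < \alpha$, default $\alpha = 0.05$) negative
correlation are *aggressive* (higher value, shorter survival); significant
positive ones are *protective*; the rest are excluded.  Censoring status is
ignored at this stage: the correlation uses observed follow-up time.  This
is defensible exactly when censored follow-up is long relative to the
outcome horizon (as in the motivating cohort, where censored patients had
follow-up beyond the 60-month boundary); with early censoring the
correlations would be biased and Kaplan--Meier/log-rank screening
(`kaplan_meier()`, `logrank_test()`) should carry the weight instead.

**Scale normalisation.** Variables live on different ranges (N on 0--3,
M on 0/1, grades on 1--4), so each value is divided by its number of
possible realizations before weighting (`scale_value()`): by two for M and
histology, by four for the others.

**The score.** With aggressive variables $x_i$ (weights
$w_i = |r_S(x_i, t)|$) and protective variables $y_j$ (weights
$v_j = r_S(y_j, t)$), a patient's score is the ratio of weighted averages

$$\mathrm{ISIR} \;=\; \frac{\sum_i w_i \tilde x_i \,/\, \sum_i w_i}
                           {\sum_j v_j \tilde y_j \,/\, \sum_j v_j},$$

with $\tilde x$ the scaled values.  Large scores mean the aggressive side
dominates the protective side: high risk.  The weighted-average
normalisation makes the score invariant to rescaling all weights on either
side; `normalize = FALSE` switches to raw weighted sums for users who want
the unnormalised ratio.  The score requires at least one protective
variable (the denominator); a cohort without a significant protective
correlation has no defined score and the fit fails with an explicit error
rather than degenerating.

**Risk classes.** Two three-class presets are shipped: the definitional one
(low $\le 0.25$, high $\ge 0.5$, inclusive outer bands) and a coarser
reporting preset (low $< 0.4$, high $> 0.8$, strict bands, boundaries to
intermediate).  The binary split is good/bad at 0.5, with a score exactly
at the cut-off counted as good.

## Evaluation

Patients are anchored to three outcome groups by observed time: $\le 12$
months, $\ge 60$ months, and the ambiguous remainder (boundaries inclusive
on the outer groups; a patient censored at or beyond 60 months has
demonstrably survived 60 months).  Discrimination is summarised by the ROC
curve and AUC for $\le 12$ versus $\ge 60$ (Mann--Whitney formulation, half
credit for ties; mid-group patients excluded), by risk-class ×
survival-group contingency tables with sensitivity/specificity reported as
numerator/denominator fractions, and by the *pooled accuracy*: the
proportion of correctly classified patients among those with a clear
outcome (bad ∧ $\le 12$ plus good ∧ $\ge 60$).

Validation uses leave-one-out cross-validation that repeats the **whole**
pipeline per fold — re-screening and re-weighting on the $n-1$ training
patients — so the selection uncertainty is priced in.  A fold whose
training set yields no significant protective variable is recorded as
unclassifiable and reported, never silently dropped; the accuracy
denominator is the classifiable clear-outcome patients, with the
unclassifiable count alongside.  A `weights-fixed` mode (fit once, score
everybody) is available as the resubstitution comparison.

## The Cox comparator

The conventional alternative is the proportional-hazards model
$\lambda(t, X) = \lambda_0(t)\exp(X\beta)$ with automatic backward
elimination: fit by partial likelihood (Breslow tie handling, the SAS PHREG
default; Efron optional), repeatedly remove the variable with the largest
Wald p-value while it exceeds 0.05 (ties broken by candidate-list order,
making elimination deterministic), refitting after each removal.  Patients
are ranked by the raw linear predictor $X\beta$ on the original coding —
the baseline hazard is never estimated, since classification only needs the
ordering and fixed cut-offs (binary at $-5.5$; three classes at
$-6 / -4.5$, strict bands).  Partial-likelihood fitting is delegated to
`survival::coxph()`; elimination, scoring and classification are package
code.  Non-convergence (monotone likelihood under separation) is detected
via unbounded coefficients and reported as an error naming the variable.

## The synthetic cohort generator

There is no deposited patient-level dataset, so the package ships a
generator whose *defaults are the study conditions*: 63 patients, the
pooled covariate margins of the motivating cohort (e.g. metastasis in
10/63; CD68 almost entirely grades 2--3 at 3/63 vs 60/63), target
covariate--survival Spearman correlations $(T\,{-0.55}$, $N\,{-0.41}$,
$M\,{-0.37}$, CD68 $+0.32$, Gas6 $+0.31$, Notch3 $+0.23$, Cox2 $+0.25$,
MMP2 and histology $0)$, exponential survival with median 25 months, and
administrative censoring at 60 months, which gives an expected censored
fraction $e^{-60\ln 2/25} \approx 0.19$ (about 12/63) with all censored
follow-up exactly at the 60-month boundary.

Mechanically it is a one-factor Gaussian copula.  Each patient has a latent
prognosis factor $Z_0$; covariate $j$ has latent
$Z_j = \rho_j Z_0 + \sqrt{1-\rho_j^2}\,\varepsilon_j$ discretized at its
marginal thresholds; survival has its own latent
$Z_T = \rho_T Z_0 + \sqrt{1-\rho_T^2}\,\varepsilon_T$ mapped through the
exponential quantile function, so the marginal survival law is exactly
exponential while survival remains a *noisy* function of the factor.  The
factor structure keeps the implied correlation matrix positive definite by
construction and is the minimal structure consistent with specifying only
covariate--survival targets.

A few calibration points deserve notice:

* **Attenuation.** Discretizing a latent normal onto a few (tied) ordinal
  categories shrinks its rank correlation with any continuous partner, and
  heavily skewed margins cap it outright (a binary split at probability
  $p$ cannot exceed roughly $\sqrt{3p(1-p)}\cdot S(\rho_T)$).  There is no
  clean closed form under ties, so `calibrate_copula()` inverts the mapping
  by pilot Monte Carlo (200,000 draws, common random numbers, bisection)
  and errors when a target exceeds the attainable bound, reporting that
  bound.
* **Survival noise.** $\rho_T = 0.93$ by default: it is the smallest round
  value under which *every* default target stays attainable — the binding
  constraint is CD68, whose 3/63 vs 60/63 margin combined with the $+0.32$
  target leaves little headroom.  Larger $\rho_T$ makes survival
  unrealistically predictable from the covariates; smaller makes the
  default targets infeasible.
* **Censoring ties.** Calibration targets the correlation with the
  *uncensored* event time.  The administrative window ties the top ~19% of
  observed times at 60 months, which mildly attenuates realized
  observed-time correlations (most visibly for the protective markers,
  whose high grades concentrate among long survivors).

What the generator does **not** emulate: inter-covariate dependence beyond
the shared factor (real T and N are directly dependent), non-exponential
survival shapes (real cohorts show long-survivor tails), staggered accrual
(censoring times here are a single administrative window), and any
measurement error in the gradings.  Passing tests on synthetic cohorts
therefore demonstrate that the estimators recover the structure they
assume, not that the score will transport to an arbitrary clinical cohort.

## Numerical and interface choices

* Spearman p-values: t approximation throughout; an exact full-permutation
  option exists for $n \le 8$ (40,320 permutations), where the
  approximation is least trustworthy and enumeration is still cheap.
* A constant candidate has an undefined correlation: `spearman_survival()`
  errors, while the screening stage records the candidate as excluded with
  `r_s = NA` so that cohort-level pipelines are not derailed by a
  degenerate margin (possible at $n = 63$ for the highly skewed markers).
* Metastasis is coded 0/1 (absent/present) with divisor 2, matching the
  usual clinical coding; its scaled values are $\{0, 0.5\}$.
* Cut-off boundaries follow the definitions exactly: $\le$ / $\ge$ for the
  definitional ISIR preset and the binary splits, strict inequalities for
  the reporting presets, boundaries falling to intermediate.
* Backward elimination uses Wald p-values per variable (the default
  display of the standard PHREG-style output); convergence failures are
  surfaced, not papered over.
* All randomness in the generator flows through `set.seed(config$seed)`;
  identical configurations reproduce byte-identical cohorts and downstream
  tables.
* Missing covariate values are rejected at cohort validation, never
  imputed: at $n \approx 63$, imputation would visibly distort the
  screening correlations that *are* the model.

Test-suite problem sizes were chosen to make sampling error small relative
to the asserted tolerances while keeping the default run fast: 5,000
patients for parameter-recovery checks (Spearman sampling error
$\approx 0.014$), 100 seeds for the recovery rate, 200 replicate cohorts of
63 for the cross-validated accuracy distribution, 500 patients for the Cox
log-hazard-ratio consistency check.

## A worked run

```{r example}
cfg <- simulation_config(n = 63, seed = 2)
cohort <- generate_cohort(cfg)
summary(cohort)

fit <- fit_isir(cohort)
print(fit)

cv <- loo_cross_validate(cohort)
print(cv)

cox <- fit_cox_backward(cohort)
print(cox)
```

## Known limitations

* ISIR ignores censoring in its correlations; it is only trustworthy when
  censoring is confined to long follow-up.
* Correlated predictors are double-counted: two near-duplicate aggressive
  markers each receive full weight, unlike in a regression.  The score has
  no mechanism for interactions either.
* The undefined-score failure mode (no significant protective variable) is
  structural: cohorts with weak protective signal produce unclassifiable
  cross-validation folds, and the package reports rather than hides them.
* The 0.25/0.5 and 0.4/0.8 cut-offs are conventions inherited with the
  score definition, not quantities re-estimated per cohort.
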