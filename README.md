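# isir — correlation-weighted integrated risk scores for survival cohorts

`isir` is an R package for clinicians and biostatisticians who want to
condense several ordinal prognostic variables — tumour staging (T, N, M),
histology, immunohistochemical biomarker gradings — into a single,
transparent risk score for each patient, and to evaluate that score against
observed survival.

## The score

Candidate variables are screened by their Spearman rank correlation
(mid-ranks, t-approximation p-values) with survival time.  Significantly
negatively correlated variables are *aggressive* ($x_i$, weights
$w_i = |r_S(x_i,t)|$), significantly positively correlated ones are
*protective* ($y_j$, weights $v_j = r_S(y_j,t)$).  After dividing every
value by its number of possible realizations ($\tilde x = x/|\mathcal{X}|$),
the Integrated Score for Individual Risk is the ratio of weighted averages

$$\mathrm{ISIR} = \frac{\sum_i w_i \tilde x_i / \sum_i w_i}
                       {\sum_j v_j \tilde y_j / \sum_j v_j},$$

with large values indicating high risk.  Scores map to risk classes
(low $\le 0.25$ / high $\ge 0.5$, or the coarser $0.4/0.8$ reporting
preset) and to a binary good/bad split at 0.5.

Around the score the package provides:

* cohort I/O and validation (`read_cohort()`, `variable_spec()`);
* univariate screening: Spearman (`spearman_survival()`), Kaplan–Meier
  (`kaplan_meier()`), log-rank (`logrank_test()`);
* fitting and application: `fit_isir()`, `isir_model()` (published
  weights), `predict()`, `classify_risk()`, `classify_binary()`;
* validation: leave-one-out cross-validation with per-fold re-screening
  (`loo_cross_validate()`), ROC/AUC for ≤12- vs ≥60-month survivors
  (`roc_auc()`), classification tables and pooled accuracy;
* a Cox proportional-hazards comparator with automatic backward
  elimination and linear-predictor risk classes (`fit_cox_backward()`,
  `cox_score()`, `classify_cox()`);
* a Gaussian-copula cohort simulator whose defaults emulate a 63-patient
  NSCLC-style study population (`simulation_config()`,
  `generate_cohort()`, `calibrate_copula()`);
* a command-line front door (`inst/cli/isir.R`, `isir_cli()`).

## A worked example

```r
library(isir)

cohort <- generate_cohort(simulation_config(n = 63, seed = 2))
fit <- fit_isir(cohort)
print(fit)
#> Integrated Score for Individual Risk (ISIR)
#>   fitted on 63 patients, alpha = 0.05
#>   aggressive (numerator): T (0.639), N (0.252)
#>   protective (denominator): CD68 (0.254), Gas6 (0.393), Cox2 (0.259)
#>   risk classes: preset 'methods'; binary cut-off 0.50 (good <= cutoff)

cv <- loo_cross_validate(cohort)
print(cv)
#> Leave-one-out cross-validation of ISIR (refit mode), n = 63
#> Held-out binary classification vs survival groups:
#>       le12 mid ge60 total
#> good     0   7    7    14
#> bad     19  28    2    49
#> total   19  35    9    63
#> sensitivity (bad | le12): 19/19 (100%)   specificity (good | ge60): 7/9 (78%)
#> Pooled accuracy among clear-prognosis patients: 26/28 = 92.9% (~93%)

roc_auc(fit$fitted$isir, fit$fitted$survival_group)
#> ROC for <=12-month (n=19) vs >=60-month (n=9) survivors: AUC = 0.980
```

Reading the output: on this simulated cohort the screen kept T and N as
aggressive variables and CD68, Gas6 and Cox2 as protective ones (at n = 63
the screen's selections fluctuate around the generator's targets — that is
the point of validating with per-fold re-screening).  Held out one at a
time, all 19 short survivors and 7 of the 9 long survivors were classified
correctly, a pooled accuracy of 26/28; the in-sample AUC separating short
from long survivors was 0.98.

The same pipeline runs from a shell:

```sh
Rscript inst/cli/isir.R simulate --n 63 --seed 2 --out run/
Rscript inst/cli/isir.R fit      --cohort run/cohort.csv --spec run/variable-spec.json --out run/
Rscript inst/cli/isir.R crossval --cohort run/cohort.csv --spec run/variable-spec.json --out run/
```

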