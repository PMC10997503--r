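---
title: "Methods: Cox prognostic indices for pediatric B-ALL relapse risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Cox prognostic indices for pediatric B-ALL relapse risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdpi)
```

## The problem

Treatment intensity in pediatric B-cell acute lymphoblastic leukemia
(B-ALL) is set by relapse-risk stratification. Conventional algorithms
dichotomize each risk factor (white blood cell count above or below
50 x 10^9/L, minimal residual disease above or below 0.01%, and so on)
and combine the categories into a handful of risk groups. A prognostic
index instead keeps the risk factors continuous and weights them by the
coefficients of a multivariable Cox proportional-hazards model for
relapse-free survival (RFS), measured from end of induction (EOI). The
index for a patient with covariate vector $x$ is the uncentered linear
predictor

$$\mathrm{PI} = \beta^\top x,$$

and higher values mean higher predicted relapse hazard. This package
implements the full life cycle of such an index: covariate
transformation, scoring with published or refit coefficient sets, model
development with diagnostics, a multi-step validation battery, optimal
discretization into ordered risk groups, and survival-curve comparison
of competing risk-group schemes — together with a synthetic cohort
generator so that every step can be exercised without access to
restricted clinical-trial data.

## Covariates and transformations

The full eight-covariate relapse model uses:

| covariate | meaning | transform |
|---|---|---|
| `tau_d29` | end-of-induction (day 29) marrow MRD | $\tau(\cdot)$, below |
| `tau_d8`  | day-8 peripheral-blood MRD | $\tau(\cdot)$ |
| `frg`, `urg` | favorable / unfavorable genetics flags | 0/1, mutually exclusive |
| `wbc_log` | presenting WBC, 10^9/L | natural log |
| `cns2`, `cns3` | CNS involvement dummies vs CNS1 | 0/1 |
| `age` | age at diagnosis | years, untransformed |

MRD is kept internally on the fraction scale (0.01% is `1e-4`). The MRD
transform is a floored negative natural log:

$$\tau(m) = \begin{cases} -\ln m & m \ge 10^{-5} \\ -\ln 10^{-6} = 13.8155 & m < 10^{-5}, \end{cases}$$

so that all values below the quantification threshold of flow cytometry
— including true zeros — share one ceiling value, reported as 13.82 at
two decimals. Higher $\tau$ means less disease. The floor
(`floor_fraction = 1e-6`), the threshold (`cap_threshold = 1e-5`) and
the log base are arguments of `tau_mrd()`, because assay generations and
study groups differ in their detection limits; the defaults reproduce
the published ceiling. Internally all transforms keep full floating
precision; two-decimal values such as 13.82 are presentation rounding
only. Consequently the worked example of the shipped COG index scores
$-2.0996$ at full precision and $-2.1002$ when evaluated with the
two-decimal $\tau = 13.82$, as printed summaries do; both fall well
inside the same risk group.

## Coefficient sets as configuration

Published index equations ship as JSON in
`inst/extdata/coefficient_sets.json`, not as code constants: the UKALL
four-covariate relapse index (with its good-risk/high-risk cytogenetics
terms mapped onto this schema's `frg`/`urg` flags — the mapping is part
of the config, so alternative genetic definitions are a config edit),
the same model refit on COG data, and the eight-covariate COG index
with its risk-group cutpoints. `hazard_ratios()` reports
$e^\beta$ per term; note that published tables sometimes exponentiate
unrounded coefficients, so a printed hazard ratio can differ from
$e^{\text{printed coefficient}}$ in the last decimal (the shipped COG
set's `urg` term is such a case: $e^{0.644} = 1.90$ against a printed
1.91).

## Model fitting and diagnostics

`fit_cox()` maximizes the Cox partial likelihood via
`survival::coxph()` with Efron tie handling by default (Breslow is
available for cross-checking against other toolchains; the two agree
exactly when no event times are tied). Convergence uses Newton
iterations with relative log-likelihood tolerance `1e-9` and at most
100 iterations; non-convergence and singular designs are errors, never
silent results. The linear predictor is deliberately **uncentered** so
that scores reproduce printed equations verbatim; the baseline survival
from `baseline_survival()` is referenced to $x = 0$ accordingly, so
$S(t \mid x) = s_0(t)^{\exp(\beta^\top x)}$ without further shifting.

Proportional hazards are examined with scaled Schoenfeld residuals and
a per-covariate zero-slope test against untransformed time
(`ph_diagnostics()`), and influence with per-subject delta-beta
(dfbeta) values, which approximate the coefficient change if the
subject were removed. Nested models (for example, testing a group of
interaction terms, or the added value of day-8 MRD on top of the
four-covariate model) are compared with the likelihood-ratio test
`lrt_nested()`.

## The validation battery

External validation of a coefficient set on new data
(`validate_pi()`) follows four steps:

1. **Calibration slope** — the log-hazard coefficient of the score in a
   univariable Cox refit, with a Wald test of slope $= 1$. Slopes below
   one indicate weaker discrimination in the new population.
2. **Discrimination** — Harrell's concordance index over usable pairs
   (the earlier time must be an event; tied scores credit 0.5; pairs
   tied on time with two events are usable at 0.5 credit, and an
   event/censoring time tie treats the censored subject as surviving
   past it).
3. **Coefficient equality** — Wald quadratic form
   $(\hat\beta - \beta_0)^\top \hat V^{-1} (\hat\beta - \beta_0)$
   comparing the refit coefficients to the published ones. The refit
   covariance alone is used, treating the reference as fixed constants;
   this understates the variance of the difference when the reference
   was itself estimated, and is documented as an approximation.
4. **Kaplan-Meier curves within score-defined groups**, compared by
   log-rank.

Internal validation (`bootstrap_optimism()`) is Harrell's bootstrap:
refit on each resample, score both the resample and the original data,
and subtract the mean apparent-minus-test gap ("optimism") from the
apparent concordance. Resample refits in small samples are unstable by
design — that instability is what optimism measures — so their
convergence warnings are silenced and only hard refit failures are
counted (more than 10% failing is an error). Calibration curves bin
patients by score (deciles by default) and compare the mean predicted
event-free probability at a horizon, $s_0(h)^{\exp(\mathrm{PI})}$, with
the within-bin Kaplan-Meier estimate; with one bin this degenerates to
the marginal comparison. "Smoothing" is equal-frequency binning here;
the bin count is an argument.

## Risk groups by concordance probability

Discretizing the index into $k$ ordered groups uses the Gönen-Heller
concordance probability estimate (CPE). For linear predictors
$\eta_i$, each unordered pair contributes
$1/(1 + e^{-|\eta_i - \eta_j|})$; `cpe()` averages over pairs with
distinct values (tied pairs excluded, 0.5-credit inclusion by flag) and
returns 0.5 when all values are tied. The estimate never falls below
0.5.

`find_cutpoints()` searches exhaustively over $(k-1)$-tuples of
candidate thresholds. Candidates sit at quantile positions of the score
but are placed **midway between adjacent order statistics**, so that a
candidate always exists inside any empty stretch of the score
distribution (where the natural cutpoint lies). For each feasible tuple
(every group at least `min_group_frac` of patients, default 5%), the
outcome is refit on the ordered-group indicators and the CPE of the
fitted group linear predictors is the objective; the maximizing tuple
wins, with ties broken deterministically toward the first tuple in
enumeration order. Two design points deserve emphasis:

* **The objective refits on group indicators** rather than scoring the
  raw categorized index, because the CPE is defined on a model's linear
  predictors. The objective function is isolated so alternatives can be
  swapped in.
* **Tie handling differs from `cpe()`'s default.** A grouped model ties
  every within-group pair. Excluding tied pairs removes group sizes
  from the objective entirely, and the search then degenerates toward
  sliver groups whose noise-inflated coefficients maximize the average
  between-group kernel (observed numerically: a 29/29/29/393 partition
  of four equal clusters scored 0.841 under exclusion against 0.790 for
  the true partition, while under half-credit inclusion the true
  partition wins 0.718 to 0.609). `find_cutpoints()` therefore defaults
  to `ties = "half"`, which keeps the estimate size-aware and preserves
  the 0.5-means-no-discrimination convention; both options are
  available on both functions.

At realistic sizes the objective is flat across a between-cluster gap
(any cut in the gap induces the same partition), so the recovered
cutpoint is identified only up to sampling noise of a few order
statistics at the gap edges; the tests exercise recovery in a regime
(four clusters of 1000, hazard steps of 1.2 on the log scale) where the
argmax lands in the gap reliably.

`assign_risk_group()` uses left-open/right-closed intervals — a score
exactly on a cutpoint takes the lower-risk label — and the shipped
default cutpoints $-1.377, -0.589, 0.093$ define the Low, Standard,
Intermediate and High groups of the COG index. Competing schemes are
compared with `crosstab_riskgroups()`: contingency counts plus
per-cell Kaplan-Meier estimates at a horizon, suppressing estimates in
cells under 25 patients (the conventional reliability floor). The
clinical comparator scheme is a first-match-wins rules engine over
cohort fields (`classify_cog_clinical()`); the shipped rule set is an
**approximation** assembled from publicly described factors (NCI risk,
genetics flags, MRD thresholds, CNS status), because the exact trial
algorithm tables are not public — it is labelled synthetic in its
filename and should be treated as illustrative.

## Endpoints

`derive_endpoint()` maps raw event bookkeeping to outcomes measured
from EOI: RFS (relapse or death in remission are events; second
malignant neoplasms censor at their time), DFS (SMN also an event) and
OS (death from any cause). Induction deaths and failures never enter
the RFS/DFS cohorts; they are excluded with a reported count. A single
`event_type` column cannot express death after relapse, so the schema
carries optional `death_time`/`death_flag` columns used only for OS;
without them OS falls back to the deaths expressible in `event_type`.
Missing covariates are handled by complete-case analysis relative to
the coefficient set in use, with the number of dropped records
reported.

## The synthetic cohort generator

`simulate_cohort()` emulates the covariate structure of the combined
COG B-ALL trial population: mutually exclusive genetics flags (45.4%
favorable, 5.9% unfavorable), CNS1/2/3 at 87.9/10.4/1.3 (normalized),
log-normal WBC with median 8.7 x 10^9/L (log-scale SD 1.4, set to
reproduce the reported range at the reported cohort size), age from a
log-normal with median 4.83 years truncated to 1.0-30.8 (log-scale SD
0.62), and day-8/day-29 MRD drawn from the observed four-category
frequencies with log-uniform values within category and a Gaussian
copula (rank correlation parameter 0.5 — the two time points are known
to correlate, but no value is published) linking the two draws.
NCI risk is derived from the standard age/WBC criteria rather than
drawn, so it is internally consistent with the other covariates.

Event times follow the proportional-hazards model
$S(t \mid x) = S_0(t)^{\exp(\beta^\top x)}$ with a Weibull baseline of
shape 0.9 — mildly decreasing hazard, the early-relapse-heavy shape
typical of this disease; shape 1 recovers the exponential — whose scale
is calibrated numerically (`calibrate_baseline_scale()`) so the
marginal 5-year RFS hits a configurable target, 0.90 by default.
Censoring is uniform on 4-12 years, reflecting staggered accrual with
several years of minimum follow-up. Event bookkeeping mirrors the
reported frequencies: 84/16 relapse vs remission-death split, 0.8%
induction deaths, 0.5% induction failures, 23.6%/3.4% missingness in
day-8/day-29 MRD, a 62.3% training-label fraction, and post-relapse
death (30%, mean one additional year) feeding the OS columns. The
generating linear predictor and the uncensored event time are returned
as columns `true_lp` and `latent_event_time` for use as ground truth.

What the generator does **not** emulate: dependence between the
covariate blocks (genetics, CNS, WBC, age and MRD are drawn
independently apart from the MRD copula, whereas real genetics and MRD
are correlated), SMN events, treatment arms and trial-specific accrual,
assay-level MRD structure, and any joint distribution of genetics with
NCI risk beyond the derived age/WBC rule. Tests passing on synthetic
cohorts therefore demonstrate the correctness of the estimators and
procedures under a proportional-hazards truth, not the clinical
performance of any index on real patients.

## Numerical conventions and degenerate inputs

* Survival step functions are right-continuous; `survival_at()`
  returns 1 before the first event time.
* Event/censoring ties at one time treat events first (standard
  product-limit convention).
* Five-year estimates are read at $t = 5$ exactly; when a group's
  follow-up ends earlier the last value carries forward and
  `km_at_horizon()` flags truncation.
* Zero events, constant scores, constant or collinear design columns,
  fewer than three events for diagnostics, horizons beyond follow-up
  and infeasible group constraints are all errors with named causes,
  not silent results.
* All simulation is driven by explicit integer seeds; a fixed seed
  reproduces cohorts and bootstrap results bit for bit.

## Problem sizes used by the test suite

The suite exercises the asymptotic properties at sizes chosen to make
the Monte-Carlo bands tight while keeping a laptop run comfortable:
coefficient recovery and interval coverage on 25 cohorts of 20,000;
calibration-slope recovery at 10,000; bootstrap optimism with B = 200
at 5,000 (low overfit) and 30 (overfit); oracle equivalence of the
concordance measures at up to 200 (Harrell C) and 500 (CPE) subjects;
cutpoint recovery on four clusters of 1000. The reference analysis
scale (B = 1000 bootstrap resamples, cohorts above 20,000) is fully
supported by the same code paths.

## Known limitations

* The coefficient-equality test ignores the sampling variance of the
  published reference coefficients.
* The rules-engine default is an approximate reconstruction, not the
  actual trial algorithm.
* No competing-risks machinery: SMN and death in remission are handled
  by censoring/event conventions per endpoint, not cumulative-incidence
  estimation.
* Time-varying covariates, stratified baselines and penalized fits are
  out of scope.
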