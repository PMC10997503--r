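# mrdpi

Cox proportional-hazards prognostic indices for relapse risk in
pediatric B-cell acute lymphoblastic leukemia (B-ALL): covariate
transformation, risk scoring with published coefficient sets, model
development and diagnostics, a multi-step external/internal validation
battery, concordance-probability-optimal risk-group cutpoints, and
Kaplan-Meier comparison of risk-group schemes. A built-in synthetic
cohort generator emulates the covariate structure of the COG trial
population, so the entire workflow runs without access to restricted
clinical-trial data.

## The science in one paragraph

Conventional B-ALL risk stratification dichotomizes each prognostic
factor; a prognostic index instead weights the factors continuously via
the linear predictor of a Cox model for relapse-free survival measured
from end of induction, `PI = Σ βᵢ xᵢ`. The covariates are
end-of-induction (day 29) and day-8 minimal residual disease through a
floored negative-log transform `τ(m) = −ln m` (ceiling 13.82 below the
10⁻⁵ quantification threshold), favorable/unfavorable genetics flags,
log WBC, CNS-status dummies and age. Validating an index on new data
checks the calibration slope (the coefficient of the index in a
univariable Cox refit, ideally 1), Harrell's concordance index, a Wald
test of coefficient equality against the published values, and
Kaplan-Meier separation of score-defined groups; internal validation
subtracts bootstrap optimism. The continuous index is discretized into
ordered risk groups at the cutpoints maximizing the Gönen–Heller
concordance probability estimate (CPE) of an ordered-group refit.

## Worked example

```r
library(mrdpi)

# a patient: favorable genetics, undetectable MRD at both time points,
# WBC 10 x 10^9/L, CNS1, age 4 — scored with the shipped COG index
# (tau at the printed two-decimal ceiling 13.82)
cog <- pi_coefficients("published_cog")
x <- c(tau_d29 = 13.82, tau_d8 = 13.82, frg = 1, urg = 0,
       wbc_log = log(10), cns2 = 0, cns3 = 0, age = 4)
score_pi(cog, x)
#> [1] -2.100237
assign_risk_group(score_pi(cog, x), cog_cutpoints())
#> [1] Low
#> Levels: Low < Standard < Intermediate < High
```

The score −2.1002 sits far below the first cutpoint −1.377, so the
patient falls in the Low relapse-risk group. The same pipeline on a
synthetic cohort, end to end:

```r
coh <- simulate_cohort(sim_config(n = 2000, seed = 3))
v <- validate_pi(cog, coh, endpoint = "rfs")
v
#> External validation (RFS endpoint), n = 1453 (526 dropped)
#>   calibration slope: 1.078 (SE 0.089), p(slope = 1) = 0.381
#>   C-index: 0.701
#>   coefficient equality: chi2(8) = 8.18, p = 0.417
#>   log-rank across score groups: chi2(3) = 104.76, p = 1.47e-22
```

Because the cohort was generated from the shipped coefficients, the
slope is compatible with 1 and the equality test does not reject; the
C-index near 0.7 reflects genuine discrimination, and the dropped
records are the complete-case exclusions for missing MRD. A
command-line wrapper over the same functions lives in
`inst/cli/mrdpi.R` (`simulate`, `score`, `validate`, `develop`,
`cutpoints`, `crosstab`).

See `vignettes/prognostic-index-methods.Rmd` for the full methods
account: transforms, validation battery, cutpoint search, generator
design and limitations.

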