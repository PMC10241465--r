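# pdisim

Comparative outcome studies of advanced chronic kidney disease (CKD) face a
structural problem: patients managed conservatively (CM, without dialysis)
have no dialysis start date, so there is no natural day on which their
follow-up for "post-dialysis" outcomes begins. The **putative dialysis
initiation (PDI) time** resolves this by asking when each CM patient's
kidney function, measured by eGFR, *would* have reached a dialysis-level
threshold, and using that day as their start of follow-up.

`pdisim` is for biostatisticians and nephrology-outcomes researchers who
want to estimate PDI times from longitudinal eGFR data and to study, by
simulation, how well the estimation works and how it propagates into
survival estimation.

## The model and estimators

eGFR decline is modeled with subject-specific lines,

    Y_ij = (β₀ + b₀ᵢ) + (β₁ + b₁ᵢ) t_ij + e_ij,   (b₀ᵢ, b₁ᵢ) ~ N(0, Σ),

and, for a threshold ỹ (default 10 mL/min/1.73m²), a subject line with
intercept γ₀ and slope γ₁ crosses it on day t* = (ỹ − γ₀)/γ₁. The package
estimates each subject's line two ways:

* **LR** — per-subject ordinary least squares (unstable with few visits);
* **LME** — a REML linear mixed model fitted to all subjects jointly, with
  subject lines formed as fixed effects + BLUPs (empirical-Bayes shrinkage
  stabilises poorly determined slopes).

Estimated PDI days can then anchor "observed" survival durations: the
calendar outcome day min(true PDI + latent follow-up, study end) minus the
estimated PDI day, with administrative censoring at the study end
(`construct_observed_survival()`), summarised by Kaplan-Meier curves and
reverse-KM median follow-up.

## Worked example

Simulate a cohort, estimate PDI days both ways, and compare with the truth:

```r
library(pdisim)

set.seed(1)
cohort <- simulate_cohort(pop_params(), visit_schedule(), n = 1000)
cohort
#> Simulated CKD cohort: 1000 subjects, 8667 eGFR records
#>   observations per subject: min 6, median 8, max 13
#>   7 subject(s) start at or below the threshold (true PDI <= 0)

fit <- fit_lme(cohort$data)
fit
#> Linear mixed effects fit (REML), random intercept + slope
#>   fixed effects : beta0 = 25.04, beta1 = -0.01096 /day
#>   variance comp.: sigma1 = 6.518, sigma2 = 0.001066 /day, rho = 0.582, sigma_e = 1.985
#>   1000 subjects; converged: TRUE; REML logLik -20700.95

est_lme <- estimate_pdi_lme(fit, threshold = 10)
est_lr  <- estimate_pdi_lr(cohort$data, threshold = 10)

pdi_mad(cohort$truth$true_pdi_day,
        est_lme$pdi_day[match(cohort$truth$subject_id, est_lme$subject_id)])
#> [1] 73.49687
#> attr(,"n_dropped")
#> [1] 0
pdi_mad(cohort$truth$true_pdi_day,
        est_lr$pdi_day[match(cohort$truth$subject_id, est_lr$subject_id)])
#> [1] 131.8595
#> attr(,"n_dropped")
#> [1] 0
```

The mixed-model estimator misses the true threshold-crossing day by about
73 days on average in this cohort, versus about 132 days for per-subject
regression — the stabilisation that motivates the LME approach. A full
Monte Carlo study replicates this across datasets:

```r
cfg <- study_config(n_subjects = 1000, n_datasets = 50, master_seed = 1)
summarize_study(run_study(cfg))
#> PDI estimation study: 50 replicate(s)
#> Per-dataset mean absolute deviation (days):
#>  method   min    q1 median  mean    q3   max  sd
#>     LME  65.9  69.2   70.2  70.5  71.7  75.6 2.2
#>      LR 113.7 120.5  124.7 124.1 127.6 137.9 5.4
#> Observations per subject (averaged over replicates): min 6.0, median 8.96, max 13.0
```

A command-line interface wrapping the same functions ships in
`inst/cli/pdisim.R` (subcommands `simulate`, `estimate`, `survival`,
`study`; YAML configuration mirroring `pop_params()` / `visit_schedule()` /
`survival_config()` field names).

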