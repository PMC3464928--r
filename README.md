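# circshape

Shape-invariant harmonic Poisson models for circadian activity-count data.

## The problem

Wrist actigraphy records physical activity as non-negative counts in short
epochs around the clock for days at a time. A recurring question in
circadian epidemiology is whether groups of people — say, obese versus
non-obese adolescents — differ in the *features* of their daily activity
rhythm: its overall level, its amplitude, and its phase (whether the whole
pattern is shifted to later or earlier clock times). Answering it requires
a model for longitudinal *count* outcomes in which those three features are
explicit parameters that can be compared across groups, with covariate
adjustment.

`circshape` is for analysts of actigraphy or similar periodic count data
who want interpretable per-subject rhythm parameters and simple, valid
group inference on them.

## The model

Counts `y_ij` for subject *i* in within-day bin *j* (time `t` rescaled so
one day is the unit interval; 15-minute bins give `t = j/96`) are Poisson
with

    log λ_ij = A_i + e^(−B_i) · f(t_ij + φ*_i)

where the common circadian shape is a sum of K harmonics,

    f(t) = Σ_{k=1..K} β_k cos(2kπ t),   β_1 ≡ 1,

so that every subject shares one shape and differs only through

* `A_i` — overall log activity level,
* `e^(−B_i)` — amplitude multiplier (larger `B` ⇒ flatter rhythm),
* `φ*_i = exp(φ_i)/(1+exp(φ_i))` — phase shift as a fraction of the
  24-hour day (inverse-logit keeps it in (0, 1)).

With K = 2 the single free shape coefficient is named `D`.

Estimation is **two-stage**. Stage 1 alternates (1) per-subject Poisson
maximum likelihood for `(A_i, B_i, φ_i)` given the shared shape — the
likelihood is profiled over a phase grid, each grid point being a
2-parameter Poisson GLM, then polished jointly — with (2) pooled maximum
likelihood for the shape coefficients given all subject parameters (a
one-parameter GLM with offset for K = 2), until convergence; each step is
a conditional maximisation so the pooled log-likelihood never decreases.
Stage 2 treats the per-subject estimates as data: a two-sample t-test for
a binary grouping, or ordinary least squares on an exposure plus
confounders. A built-in simulation engine verifies that this two-stage
t-test holds its nominal type-I error.

## Worked example

```r
library(circshape)

# a cohort of 20 subjects, group 1 phase-delayed by 0.8 on the logit scale
spec <- cohort_spec(n_subjects = 20, group_sizes = c(14, 6), n_days = 2,
                    effect_phi = 0.8)
cohort <- simulate_cohort(spec, seed = 42)

fit <- fit_cohort(cohort$series)
fit
#> Shape-invariant Poisson fit (stage 1)
#>   20 subjects, K = 2 harmonics
#>   shared shape coefficients: 0.4038
#>   pooled log-likelihood: -13213.27 after 16 outer iteration(s) (converged)

groups <- setNames(cohort$truth$group, cohort$truth$subject)
two_sample_test(fit, groups)
#> Stage-2 inference on circadian parameters
#>  parameter difference     se df p_value method n0 n1
#>          A    -0.4561 0.2438 18 0.07764 t_test 14  6
#>          B    -0.1671 0.1042 18  0.1264 t_test 14  6
#>        phi     0.6119 0.2545 18 0.02719 t_test 14  6
#> phase difference on the clock: 3.38 hours (group 1 - group 0)
```

The shared shape coefficient is recovered near its generating value
(D = 0.4). The t-test detects the planted phase delay (`phi` row,
p ≈ 0.027): group 1's rhythm sits about 3.4 hours later on the clock,
while level and amplitude do not differ significantly. Per-subject curves
can be summarised on the intensity scale:

```r
curve_summary(subject_params(fit$subjects$A[1], fit$subjects$B[1],
                             fit$subjects$phi[1]), fit$shape)
#> Curve summary: mean level 113.646, peak-to-trough amplitude 227.100, peak at 11.33 h
```

Covariate adjustment uses `adjusted_regression(fit, exposure, covariates)`;
`type1_error_study()` and `power_study()` run replicate
simulate–fit–test experiments; `read_cohort()` / `aggregate_epochs()`
ingest long-format count tables or raw 30-second epoch series; and
`run_pipeline()` drives the whole analysis from a YAML config (a thin CLI
wrapper lives in `inst/cli/circshape.R`).

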