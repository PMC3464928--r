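---
title: "Methods: the shape-invariant Poisson model and its two-stage estimator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the shape-invariant Poisson model and its two-stage estimator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circshape)
```

## The model

Activity counts in within-day bins are modelled as Poisson,
$y_{ij} \sim \mathrm{Pois}(\lambda_{ij})$, with

$$\log \lambda_{ij} = A_i + e^{-B_i}\, f(t_{ij} + \phi^*_i), \qquad
f(t) = \sum_{k=1}^{K} \beta_k \cos(2k\pi t),\ \beta_1 \equiv 1 .$$

Time is rescaled so one 24-hour day is the unit interval; bin $j$ of a
96-bin day carries its right endpoint $t = j/96$ (the first 15-minute
segment is $t = 1/96$). The model is *shape invariant*: one periodic curve
$f$ is shared by everyone, and subjects differ only through

* $A_i$ — overall log level (dimensionless log counts per bin);
* $e^{-B_i}$ — amplitude multiplier on the log-intensity scale. We follow
  the multiplicative $e^{-B}$ parameterisation throughout, so **larger $B$
  means a flatter rhythm** and $B \to \infty$ is the rhythm-free limit.
  $B$ is unbounded; the multiplier is always positive, which is what makes
  $B$ a scale on which ordinary linear inference is sensible;
* $\phi^*_i = e^{\phi_i}/(1+e^{\phi_i}) \in (0,1)$ — the phase shift as a
  fraction of the day. The inverse logit keeps the estimate inside one
  period while $\phi_i$ stays unconstrained for optimisation and stage-2
  inference.

Fixing $\beta_1 = 1$ is the identifiability normalisation: a free first
harmonic could be traded against $e^{-B_i}$.

**Phase convention.** We define the shift as $f(t + \phi^*)$ with $\phi^*$
a day fraction applied identically inside every harmonic, so the entire
curve moves rigidly — a positive $\phi^*$ moves the peak *earlier* by
$24\phi^*$ hours, and a *negative* group difference in $\phi$ means a
phase delay. One convention had to be picked because "shift" can be
written with either sign and in either radians or day fractions; this one
keeps the shape-invariance property exact for any $K$. Flipping the sign
of $\phi$ flips the convention, so no generality is lost.

Curve summaries on the intensity scale are provided by `curve_summary()`:
mean level (average of $\lambda$ over one period), peak-to-trough
amplitude ($\max \lambda - \min \lambda$), and peak clock time in hours.
Amplitude *inference* is done on $B$; the intensity-scale amplitude is a
derived display quantity.

## Stage 1: alternating estimation

The per-subject likelihoods are coupled only through the shared shape
coefficients, so estimation alternates two conditional maximisations:

1. **Subject step.** For fixed shape, each subject's $(A_i, B_i, \phi_i)$
   is estimated by maximum likelihood. For fixed phase the model is a
   Poisson GLM in $(A, C)$ with $C = e^{-B}$ and regressor
   $f(t + \phi^*)$; because the likelihood is periodic and multimodal in
   the phase, we *profile* over a grid of `phase_grid_size` (default 96)
   phase fractions, solving the 2-parameter GLM at every grid point by a
   vectorised Newton iteration, then polish the best point with a BFGS
   search over all three parameters jointly (analytic gradient). Grid
   points with $\hat C \le 0$ are discarded: a negative first-harmonic
   loading is the half-period phase-flip alias of a positive one.
2. **Shape step.** For fixed subject parameters, $\log \lambda$ is
   *linear* in $(\beta_2, \ldots, \beta_K)$ with offset
   $A_i + C_i \cos\{2\pi(t + \phi^*_i)\}$, so the pooled fit is a
   $(K-1)$-parameter Poisson GLM solved by Newton iteration with step
   halving. It never returns a shape worse than the incoming one, and it
   returns the incoming shape untouched (flagged non-identifiable) when
   the pooled curvature is near zero — no rhythm, no shape information.

Because both steps are conditional maximisations, the pooled
log-likelihood is non-decreasing across iterations; the recorded trace is
checked for this in the test suite, and a decrease would indicate a bug,
not noise.

**Initialisation and warm starts.** $A$ starts at
$\log(\bar y + 0.5/n)$, $B$ at $-\log \hat C$ from the grid, $\phi$ from
the profiled grid; the shape starts at zero (pure first harmonic). After
the second outer iteration the grid profile is skipped and each subject's
polish warm-starts from its previous estimate — the shape changes little
per iteration, and the candidate set always contains the previous
parameters, which preserves the monotone-ascent guarantee while making
replicate simulation studies affordable.

**Convergence.** The alternation stops when both the largest shape
coefficient change and the relative pooled log-likelihood change fall
below `tol` (default `1e-6`), with a warning (not an error) after
`max_outer_iters` (default 100). Typical cohorts converge in 15–20
iterations. Estimates are insensitive to `tol` well below `1e-3`.

**Degenerate data.** All-zero subjects have no finite $\hat A$; they are
excluded with a warning and listed in the result, and the fit aborts if
more than 20% of the cohort is degenerate. Constant positive counts drive
$e^{-\hat B}$ to the zero boundary; such fits are flagged (`boundary`)
and capped at $B = 35$ rather than diverging. Per-subject standard errors
from the observed information are reported for completeness; stage 2 uses
only the point estimates.

## Stage 2: inference on the estimates

The per-subject estimates are treated as data. For a binary grouping,
`two_sample_test()` performs the two-sided pooled-variance t-test on each
of $A$, $B$, $\phi$ (Welch available by flag); the pooled test is the
default because its difference/SE layout coincides exactly with OLS on a
group dummy, a correspondence the tests exploit. $\phi$ is tested on the
unconstrained scale — the scale on which it is normal-ish across subjects —
and the group difference in mean $\phi^*$ is additionally reported in
clock hours for display. `adjusted_regression()` fits OLS of each
parameter on an exposure (binary or continuous) plus covariates:
complete-case with a logged count of dropped subjects, factors expanded
against their first level, rank deficiency reported with the offending
columns named. No multiple-testing adjustment is applied across the three
parameters by default, matching the reporting convention of two-stage
circadian analyses; the three p-values are exposed so any correction can
be applied downstream.

Using estimated rather than true subject parameters could in principle
induce dependence across subjects (through the shared shape) and distort
the test's size. Rather than correcting for this analytically, the
package verifies empirically that the naive test is valid — the point of
the simulation engine.

## The synthetic-data generator

`cohort_spec()`/`simulate_cohort()` emulate a one-week actigraphy study:
96 subjects split 77/19 into two groups, 7 days × 96 fifteen-minute bins
= 672 counts per subject. Subject parameters are drawn independently (or
with a user-supplied covariance) from normals on the unconstrained
scales, group effects enter additively, and counts are Poisson draws from
the model intensity; day replicates share the within-day intensity (no
day-of-week effect). The population defaults

$$\mu_A = 4.0,\ \sigma_A = 0.4,\quad \mu_B = 0.3,\ \sigma_B = 0.2,\quad
\mu_\phi = 0,\ \sigma_\phi = 0.5,\quad D = 0.4$$

are package choices tuned for realism — day-time peaks in the low
hundreds of counts per 15-minute bin, troughs near rest, phases spread
over a few hours — not values transcribed from any dataset. Everything is
configurable and all randomness flows from a single seed.

What the generator deliberately does **not** emulate: overdispersion
(counts are exactly Poisson, so the index-of-dispersion test pins the
generator, while real actigraphy is usually overdispersed), day-of-week
structure, device non-wear or missing epochs, and autocorrelation within
a day beyond the harmonic mean structure. Passing null-validity tests on
these cohorts therefore shows the two-stage machinery is sound under the
model's own assumptions; it does not certify robustness to
overdispersion, though Poisson-score-based effect estimates are typically
robust to it in the mean structure.

`type1_error_study()` runs the full simulate → fit → test pipeline on
null cohorts and reports per-parameter rejection proportions with exact
binomial confidence intervals; `power_study()` does the same with
effects planted. Replicates whose stage-1 fit fails are dropped from the
denominator and counted separately.

## Numerical choices

* Curve summaries scan 1440 grid points per period (1-minute resolution,
  configurable); peak-time accuracy is therefore ±0.5 min, and ties at
  the grid resolution resolve to the earliest time.
* The phase grid uses midpoints $(j - \tfrac12)/G$ so the logit transform
  never hits ±∞.
* Newton steps in the grid solver are clamped to ±2 per iteration; the
  linear predictor is capped at 30 (intensities near $10^{13}$) during
  iteration to avoid overflow on wild intermediate steps.
* The generator refuses specs whose maximum log intensity exceeds 25,
  with advice to rescale, rather than silently producing astronomically
  large counts.
* Exact binomial CIs (Clopper–Pearson, via `binom.test`) are used for
  rejection rates; at 300 replicates the 99% interval around 0.05 spans
  roughly 0.02–0.10.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run a desk-scale version of the
null-validity experiment: 300 replicates of 24 subjects (19 + 5) over 2
days, judged against 99% binomial intervals; the full-scale experiment
(2000 replicates at the complete 96 × 672 design, 95% intervals) is the
same call to `type1_error_study()` with larger arguments and is left as
an overnight run. Consistency over monitoring length is checked with a
nested design — each replicate cohort is simulated for 28 days and
re-analysed on its first 1 and 7 days — because with independent cohorts
the shape coefficient is already estimated to ~3×10⁻⁴ at one week and
the 7-versus-28-day error ordering would be dominated by Monte-Carlo
noise; nesting makes the information strictly increasing within each
replicate. These sizes are the package's chosen defaults for its own
validation and are stated here so they can be scaled up deliberately.

## Known limitations

* No negative-binomial (overdispersed) likelihood yet; the likelihood
  layer is isolated so it could be swapped in.
* No within-day covariates, day effects, or random-effects joint
  estimation — the two-stage scheme deliberately avoids joint nonlinear
  mixed modelling so it stays implementable with standard components.
* Phase inference near the boundary of identifiability (nearly flat
  subjects) is fragile by nature; such subjects are flagged rather than
  down-weighted.
* The t-test/OLS stage ignores the differing precision of per-subject
  estimates; with very unbalanced monitoring lengths a weighted stage 2
  would be preferable.
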