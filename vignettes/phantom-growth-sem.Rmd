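---
title: "Phantom-variable and growth-curve SEM from published moment tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-variable and growth-curve SEM from published moment tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomsem)
```

## The estimation problem

`phantomsem` fits recursive covariance-structure models by maximum
likelihood to *sample moments* rather than raw records.  The model is held
in RAM form: a directed-coefficient matrix $A$ over all variables (observed
and latent), a symmetric matrix $S$ of exogenous variances, disturbances and
covariances, and a selector $F$ of the observed rows, so that

$$\Sigma(\theta) = F\,(I-A)^{-1} S\, (I-A)^{-\mathsf T} F^{\mathsf T}.$$

Estimates minimize the multivariate-normal discrepancy
$F_{ML} = \log|\Sigma| + \mathrm{tr}(S_{sample}\Sigma^{-1}) -
\log|S_{sample}| - p$, and $\chi^2 = (N-1)\,F_{\min}$.  Because only second
moments enter, a published descriptives table and correlation matrix are a
complete input; the packaged study (a community cohort of 227 women who had
left an abusive partner) is reproduced entirely from its printed tables.

Fitting to printed tables has one consequence worth stating up front:
correlations printed at two decimals carry rounding error of up to .005 per
cell, and with 91 correlations that input noise propagates into every
statistic.  Reproduction accuracy is therefore judged in a band attributable
to input rounding — coefficients to about ±.05, fit indices to about ±.02 —
rather than digit-for-digit.

## The packaged lifetime-abuse model

`build_whes_model()` constructs the final published structural model linking
cumulative lifetime abuse severity to cardiovascular disease risk:

* **Phantom composite.**  No instrument measures *lifetime* abuse, so the
  model defines it: child abuse (CTQ), partner abuse (ISA) and adult sexual
  assault (ASA; a 0/1 question) are standardized, each loads its own
  single-indicator latent, and the three latents send fixed unit paths into
  a phantom "Lifetime Abuse" latent.  Its explained variance is then
  $V_1+V_2+V_3+2C_{12}+2C_{13}+2C_{23}$, and its disturbance is
  *constrained* — recomputed from the current abuse (co)variances at every
  optimizer iteration — to 20% of its total variance, reflecting abuse
  sources the three instruments miss.  A `phantom$fixed` flag freezes the
  disturbance at its starting magnitude instead, for users who prefer the
  fixed-at-start convention.
* **Growth curve.**  CES-D depressive-symptom scores at five annual waves
  load on an intercept (all loadings 1) and a slope.  Slope loadings are
  fixed at 0/1/2 for waves 1–3 and free for waves 4–5
  (`free_slope_times = c(4, 5)`), letting the rate of change flatten, as the
  descriptives suggest it does.  The intercept and slope disturbances
  covary freely.
* **Measurement error by assumed reliability.**  Every indicator's error
  variance is fixed at `fraction × sample variance`, with the published
  fractions (`default_error_fractions()`): CTQ .06 (one minus Cronbach's
  alpha .94), ISA and ASA .15, the five CES-D waves .30, smoking .05, BMI
  .16, waist circumference .05, blood pressures .25, age .01.  The fractions
  are unitless shares, so the standardized solution is invariant to
  indicator rescaling.
* **Structure.**  Thirteen free structural paths: lifetime abuse to the
  depression intercept, slope, smoking, body weight and CVD risk; intercept
  to body weight; slope to smoking, body weight and CVD risk; smoking to
  body weight and CVD risk; body weight to CVD risk; age to CVD risk.  Body
  weight (BMI, waist circumference) and CVD risk (systolic, diastolic blood
  pressure) fix their first loading at 1 and estimate the second; the three
  abuse latents covary freely with each other but not with age.  That gives
  30 free parameters against 105 moments, df = 75.

The structure was reconstructed from the published evidence — the listed
direct effects (which include a direct smoking-to-CVD-risk entry), the
stated count of 13 model paths, and the df = 75 arithmetic.  Two
reconstruction facts support it independently: with both blood-pressure
loadings fixed at 1 and 25% error, the implied systolic–diastolic covariance
is capped below the sample value (an infeasible model), and the fitted
largest positive standardized residual, +1.91, reproduces the published
+1.90.

```{r fit}
fit <- fit_sem(build_whes_model(), whes_moments(),
               standardize = c("CTQ", "ISA", "ASA"))
fit
```

## Derived moments in the fixture

Two entries of the packaged descriptives table are not printed in the
source tables and are derived, with the derivation tested rather than
hidden: the SD of the binary assault indicator from its prevalence
(`binary_sd(0.388)` = 0.487), and the mean/SD of 0/1/2-coded smoking from
the category counts 75/68/84 (`categorical_moments()`, population divisor,
mean 1.040, SD 0.836).  Both use the divisor-$n$ form to match
moment-matrix usage; at $N = 227$ the $n$ vs $n-1$ distinction is far below
every tolerance in play.  Since the abuse indicators are standardized before
modeling, the derived ASA SD never enters the fitted covariance.

## Numerical choices

* **Input repair.**  Correlations printed at two decimals can make the
  assembled covariance numerically non-PD; `nearest_pd()` clips eigenvalues
  at a floor (Frobenius-nearest repair), restores a unit diagonal for
  correlation input, and records the repair magnitude on the result (for the
  packaged tables the matrix is already PD and passes through untouched).
* **Optimization.**  Quasi-Newton (`nlminb`) with an analytic gradient
  derived in RAM calculus, then Newton steps on the Hessian (finite
  differences of the analytic gradient) until the gradient maximum norm
  falls below `1e-8`; the convergence flag reports the achieved norm
  honestly.  Starting values: exogenous (co)variances at their indicator
  sample moments scaled by one minus the error fraction, structural
  coefficients at 0.1, disturbances at 50% of the reference indicator's
  variance, free growth loadings at their linear continuation.  Up to 20
  jittered restarts on non-convergence.
* **Admissibility.**  Variances are not constrained during the search,
  mirroring common SEM practice; a negative estimated variance (Heywood
  case) raises a warning and flags the fit rather than being bounded away.
* **Conventions.**  $\chi^2$ uses $(N-1)$ scaling (an `n_scale = "n"` flag
  switches); CFI/TLI use the free-variance independence baseline; the
  standardized solution uses model-implied SDs, covariance parameters are
  reported as correlations between the corresponding exogenous/disturbance
  terms (so the intercept–slope entry is the disturbance correlation), and
  disturbance variances standardize to $1 - R^2$.  Wald tests use the
  inverse observed information at the optimum; $\alpha = .05$ with no
  multiplicity correction, matching the original reporting.
* **Residuals.**  Standardized residuals are
  $(s_{ij}-\sigma_{ij})/\sqrt{(\sigma_{ii}\sigma_{jj}+\sigma_{ij}^2)/n}$.
  The source analysis does not state its residual formula, so the published
  largest residual is treated as a soft cross-check, not a target.

## Effects and bootstrap

Standardized direct effects over the structural latents decompose as
$T = (I-B)^{-1} - I$ (total) and $T - B$ (indirect); `total = direct +
indirect` holds to machine precision, and an exhaustive path-enumeration
oracle (`enumerate_paths()`) must agree with the matrix identity — the test
suite checks this on randomly generated recursive systems as well as on the
fitted model.

The original analysis bootstrapped raw records, which are not available.
`parametric_bootstrap()` therefore simulates from the fitted implied
distribution at the study size, refits each replicate through the full
pipeline (per-replicate standardization and error-fraction resolution), and
forms percentile intervals; row-resampling is used instead whenever raw
data are supplied.  Interval agreement with the published intervals is
approximate by construction, and one visible artifact of refitting under
model misfit is a small systematic shift (under .01) in the standardized
second loadings across replicates.  Percentile intervals are the default
because the original interval type is unstated.

## What the synthetic-data generator emulates

`generate_data()` draws all exogenous terms from zero-mean Gaussians with
the assembled $S$, propagates them through $(I-A)^{-1}$, and returns the
observed indicators; the default truth is the fitted study solution, so
simulation experiments probe the published regime (a zero-structural-path
truth for type-I-error studies is one `sem_params()` call away).  Optional
probit-style coarsening dichotomizes the assault indicator at the Gaussian
quantile matching the 38.8% prevalence and trichotomizes smoking at the
33.0/30.0/37.0% shares; coarsening attenuates correlations involving those
columns, which the tests verify statistically.  The generator does not
emulate non-Gaussian latents, attrition, or item-level scale construction —
so passing recovery tests demonstrate the estimator's correctness under the
model's own assumptions, not robustness to their violation.

`recovery_experiment()` refits replicated datasets and reports bias and
RMSE per free parameter.  Two deliberate conventions: (1) the fixed error
variances are constants of the generating model, not estimated quantities,
so refits hold them at their true values — re-deriving them as
`fraction × replicate variance` would inject a systematic offset whenever
the generating solution does not fit its source data exactly, which is a
property of the design, not of the estimator; (2) a parameter's recovery
scale is `max(|truth|, mean |truth| of its class)` (loading / structural /
variance / covariance), because percentage bias against a near-zero true
value is below the Monte-Carlo resolution of any finite experiment.  The
acceptance suite runs 60 replicates at $N = 20{,}000$ so the Monte-Carlo
error of the estimated bias is small against the 2%-of-scale criterion, and
500 bootstrap replicates at the study size; both finish in well under two
minutes on one CPU.

## Known limitations

* Covariance structure only: no mean structure, so the published slope mean
  (−.25) is outside the reproduction scope; no missing-data likelihood, no
  robust/scaled $\chi^2$, no categorical-data estimators (the 0/1 and 0/1/2
  indicators enter as numeric scores with assigned error, exactly as in the
  source analysis).
* Recursive (acyclic) structural systems only; single group.
* Model modification search is out of scope: only the final published
  structure is implemented, and standardized residuals are reported for
  inspection without automated modification indices.
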