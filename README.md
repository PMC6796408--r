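# phantomsem

Maximum-likelihood covariance-structure modeling (SEM) for recursive latent
models specified as explicit parameter maps, built around three constructions
that are awkward in off-the-shelf tools:

* **phantom composite latents** — a latent with no indicators of its own,
  defined by fixed unit paths from other latents, whose disturbance is
  constrained to a fixed share of its *total* variance at every iteration of
  the optimizer;
* **latent growth curves with partially free time scores** — an intercept
  factor (loadings fixed at 1) and a slope factor whose early loadings are
  fixed (0, 1, 2) while later ones are freely estimated;
* **fixed reliability-based measurement error** — single-indicator latents
  identified by fixing the loading at 1 and the error variance at
  `(1 − reliability) × sample variance` of the indicator.

Models are fitted **directly to published moment tables** (means, SDs,
correlation matrix, N), so a complete analysis can be reproduced from a
printed descriptives table and correlation matrix — no raw data needed.
The package ships the moment tables of a community cohort of 227 women who
had left an abusive partner (the Women's Health Effects Study, WHES), and the
final structural model linking cumulative lifetime abuse severity to
cardiovascular disease (CVD) risk through depressive-symptom trajectories and
risk behaviors.

## The model

For observed variables selected by `F` from the full variable set, with
directed coefficients `A` and symmetric (co)variances `S` (RAM form), the
implied covariance is

    Sigma(theta) = F (I − A)^-1 S (I − A)^-T F'

and parameters minimize the ML discrepancy

    F_ML = log|Sigma| + tr(S_sample Sigma^-1) − log|S_sample| − p ,

with `chi2 = (N − 1) F_min`, RMSEA, CFI and TLI computed against the
independence baseline.  Standardized direct effects `B` decompose into total
effects `(I − B)^-1 − I` and indirect effects (total − direct), cross-checked
by exhaustive path enumeration.  Confidence intervals come from a parametric
bootstrap: simulate N records from the fitted implied distribution, refit,
take percentile intervals.

In the packaged lifetime-abuse model, "Lifetime Abuse" is a phantom composite
of child abuse (CTQ), partner abuse (ISA) and adult sexual assault (ASA),
each standardized and carrying a fixed unit path, so the phantom variance is
`Var1 + Var2 + Var3 + 2Cov12 + 2Cov13 + 2Cov23`, plus a disturbance pinned at
20% of the total.  Depressive symptoms over five annual waves (CES-D) follow
a growth curve whose slope loadings are fixed at 0/1/2 for waves 1–3 and free
for waves 4–5.  Smoking history (never/past/current coded 0/1/2), body weight
(BMI, waist circumference) and CVD risk (systolic/diastolic blood pressure)
complete the system: 13 structural paths, 30 free parameters, df = 75.

## Worked example

```r
library(phantomsem)
study <- whes_study(bootstrap = 500, seed = 42)
print(study)
```

prints (abridged):

```
Maximum-likelihood covariance-structure fit
  chi2 = 157.97 on df = 75 (p 7.33e-08), chi2/df = 2.11
  RMSEA = 0.070  CFI = 0.929  TLI = 0.914
  converged: TRUE (max |grad| 2.3e-14, 170 iterations)
  largest |standardized residual| = 2.86 (largest positive 1.91)
  R-squared:
LifetimeAbuse  DepIntercept      DepSlope       Smoking    BodyWeight       CVDRisk
        0.800         0.206         0.002         0.142         0.054         0.407

Standardized causal effects (reference value and absolute deviation in brackets):
  DepIntercept  <- LifetimeAbuse  direct   0.454  indirect   0.000  total   0.454  [ref 0.428, dev 0.026]
  Smoking       <- LifetimeAbuse  direct   0.360  indirect  -0.006  total   0.354  [ref 0.349, dev 0.011]
  BodyWeight    <- Smoking        direct  -0.163  indirect   0.000  total  -0.163  [ref -0.153, dev 0.010]
  CVDRisk       <- BodyWeight     direct   0.533  indirect   0.000  total   0.533  [ref 0.526, dev 0.007]
  CVDRisk       <- AgeLat         direct   0.345  indirect   0.000  total   0.345  [ref 0.347, dev 0.002]
  ...

parametric bootstrap: 500/500 replicates converged (n = 227, 95% percentile intervals)
                          label estimate  lower  upper
5  b_LifetimeAbuse_DepIntercept    0.454  0.291  0.593
...
```

Reading the output: the model reproduces the published regime — severity of
lifetime abuse raises initial depressive symptoms (β ≈ .45), smoking
(β ≈ .36) and body weight (β ≈ .23); body weight (β ≈ .53) and age (β ≈ .34)
raise blood-pressure-indicated CVD risk; the direct abuse → CVD path is
negative and non-significant (β ≈ −.15, Wald p ≈ .06); 41% of CVD-risk
variance is explained.  Deviations from the published reference values
(brackets) are at the level expected from consuming correlations printed at
two decimals: coefficients agree within ±0.03, fit statistics (chi2/df 2.11
vs 1.99, CFI .93 vs .94, TLI .91 vs .92, RMSEA .070 vs .07) within the
rounding-attributable band.  The largest positive standardized residual,
+1.91, matches the published +1.90.

Other entry points: `load_moments()` / `to_covariance()` for your own moment
tables, `read_model_spec()` for user-defined models in a declarative text
format, `generate_data()` / `recovery_experiment()` for simulation studies,
and `inst/cli/phantomsem.R` as a shell front-end (`fit`, `simulate`
subcommands).

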