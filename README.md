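# twinlag

Genetically informed autoregressive cross-lagged models for twin panel
data.

## What it is for

Prospective associations between two traits — the motivating case is
cognitive ability and emotional problems measured at ages 7, 9 and 12 —
can reflect causation in either direction, or confounding by the genes and
family environments that influence both.  Twin data separate these
explanations: monozygotic (MZ) co-twins share 100% of their segregating
genes, dizygotic (DZ) co-twins 50% on average, and both share their family
environment, so the MZ/DZ contrast in cross-twin cross-trait covariance
identifies additive-genetic (A), shared-environment (C) and
nonshared-environment (E) contributions to every longitudinal path.  A
cross-lagged path that retains a nonshared-environment (E) component after
genetic and shared-environment overlap is controlled is *consistent with*
a causal effect; its absence argues against one.

`twinlag` is aimed at behavioural-genetics and developmental researchers
who want that analysis as a tested, reusable pipeline:

* **Phenotypic cross-lagged panel model** (`fit_clpm`): per interval,
  stability paths *b* (same trait across waves), cross-lagged paths *c*
  (partial regressions of each wave-(t+1) variable on both wave-t
  variables) and within-wave correlational paths *a*; standard errors are
  cluster-robust over families.
* **ACE cross-lagged SEM** (`fit_ace_clpm`): each observed variable is
  A + C + E, each component follows its own cross-lagged process with
  cross-twin correlations (1, 1, 0) in MZ and (0.5, 1, 0) in DZ pairs;
  two-group estimation by full-information maximum likelihood (missing
  waves stay in), Cholesky parameterization (variance components bounded
  at zero), multi-start BFGS from a method-of-moments initialization.
* **Path decomposition** (`decompose_paths`): every standardized path
  split into β_A + β_C + β_E = β_total by path tracing, with percentage
  shares 100·β_k/β_total and delta-method intervals; univariate h², c², e²
  per variable and wave (`variance_components`, `univariate_ace`).
* **Model reduction** (`fit_correlated_factors` + `reduce_model`):
  shared-environment cross-parameters whose rC interval covers zero are
  fixed to 0 before the structured fit, as is standard practice when C is
  weak.
* **MZ-differences design** (`make_differences`, `fit_mzdiff_clpm`):
  within-pair differences cancel A and C, corroborating E-path findings.
* **Calibrated synthetic cohorts** (`twin_preset`, `calibrate_ace_model`,
  `simulate_pairs`): generating models whose implied standardized
  solution reproduces a target set of paths, shares and variance
  trajectories exactly, plus sex/age covariates and wave-level attrition —
  the basis of all ground-truth validation, and a stand-in for
  access-restricted cohort data.
* **One-call pipeline** (`run_analysis`): exclusions → residualization →
  optional subdomain adjustment → CLPM → correlated factors → reduction →
  ACE CLPM → decomposition → saturated-model comparison → MZ differences,
  with JSON/CSV artifacts, a provenance map and a run log.

## Worked example

Simulate a cohort from the "general cognitive ability" preset, residualize
sex and age, and run the phenotypic and biometric models:

```r
library(twinlag)

model <- twin_preset("general")
pairs <- simulate_pairs(model, n_mz = 8000, n_dz = 8000, seed = 1,
                        missingness = "wave", covariates = TRUE)
panel <- residualize(pairs, traits = model$traits)
fit_clpm(panel)
```

```
Phenotypic cross-lagged panel model (16000 family clusters)
             path          type estimate    se ci_lower ci_upper     n
     g_w1 -> g_w2     stability    0.543 0.007    0.530    0.557 19879
   emo_w1 -> g_w2      crosslag   -0.104 0.007   -0.116   -0.091 19879
 emo_w1 -> emo_w2     stability    0.426 0.007    0.412    0.440 19879
   g_w1 -> emo_w2      crosslag   -0.085 0.007   -0.099   -0.071 19879
     g_w2 -> g_w3     stability    0.582 0.007    0.568    0.595 16333
   emo_w2 -> g_w3      crosslag   -0.041 0.007   -0.055   -0.027 16333
 emo_w2 -> emo_w3     stability    0.453 0.008    0.438    0.468 16333
   g_w2 -> emo_w3      crosslag   -0.075 0.008   -0.090   -0.060 16333
   g_w1 ~~ emo_w1 correlational   -0.130 0.006   -0.142   -0.117 32000
   g_w2 ~~ emo_w2 correlational   -0.160 0.008   -0.175   -0.144 19879
   g_w3 ~~ emo_w3 correlational   -0.032 0.008   -0.048   -0.016 16333
```

Higher cognition predicts lower later emotional problems and vice versa
(all four cross-lags negative), on top of strong stability.  The ACE
cross-lagged model decomposes those paths:

```r
fit <- fit_ace_clpm(panel, se = "delta")
dec <- decompose_paths(fit)
dec[dec$type == "crosslag",
    c("path", "total", "beta_A", "beta_C", "beta_E",
      "share_A", "share_C", "share_E")]
```

```
           path  total beta_A beta_C beta_E share_A share_C share_E
 g_w1 -> emo_w2 -0.083 -0.038 -0.034 -0.011  46.277  40.711  13.013
 emo_w1 -> g_w2 -0.109 -0.005 -0.079 -0.024   4.839  72.974  22.186
 g_w2 -> emo_w3 -0.089 -0.047 -0.039 -0.003  53.263  43.272   3.465
 emo_w2 -> g_w3 -0.045  0.018 -0.042 -0.022 -40.848  92.495  48.353
```

Reading the second row: of the −0.109 path from age-7 emotional problems
to age-9 cognition, shared environment carries 73% and nonshared
environment 22% — the E share is the quasi-causal signal.  (This cohort
was generated with a 19% E share on that path; shares of *small* totals,
like the last row's −0.045, are intrinsically noisy and their signed
shares should be read through their intervals.)  Univariate estimates and
fit indices:

```r
univariate_ace(panel, "g_w1")$components   #  h2 0.35, c2 0.33, e2 0.32
lrt_vs_saturated(fit)   # chisq = 146.1, df = 123, p = 0.08
```

The `vignettes/` directory documents the model, the calibration of the
shipped presets, and all numerical conventions.

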