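---
title: "Genetically informed cross-lagged models for twin panel data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetically informed cross-lagged models for twin panel data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package addresses

Cognitive ability and emotional problems co-occur across childhood, and
prospective associations run in both directions.  Observational panel data
alone cannot say whether these associations are causal: the same genes and
the same family environment may influence both traits.  Twin designs offer a
quasi-experimental handle.  Monozygotic (MZ) co-twins share all of their
segregating genetic variation, dizygotic (DZ) co-twins on average half of
it, and both types share their family environment.  Comparing MZ and DZ
cross-twin cross-trait covariance therefore separates additive-genetic (A),
shared-environment (C) and nonshared-environment (E) contributions to the
association between two traits.  A prospective path that survives after the
A and C contributions are removed — a nonzero E path — is *consistent with*
(never proof of) a causal effect, because everything twins share has been
controlled.

`twinlag` implements this program for two traits measured at three waves in
MZ/DZ twin pairs:

1. a phenotypic autoregressive cross-lagged panel model (CLPM) with
   family-clustered uncertainty,
2. a two-group ACE cross-lagged structural equation model fitted by full
   information maximum likelihood (FIML), with every path decomposed into
   A, C and E contributions,
3. a correlated-factors twin model used to locate obsolete
   shared-environment parameters before fitting the structured model,
4. the MZ-differences design as an independent corroboration, and
5. a calibrated synthetic twin-cohort generator, because the motivating
   cohort data are access-restricted; every estimator in the package is
   validated by ground-truth recovery on synthetic cohorts.

## The models

### Phenotypic cross-lagged model

Let $X_t$ and $Y_t$ be the standardized cognitive and emotional scores at
wave $t \in \{1,2,3\}$ (ages 7, 9, 12).  The CLPM contains, per interval,
*stability* paths $b$ ($X_t \to X_{t+1}$, $Y_t \to Y_{t+1}$), *cross-lagged*
paths $c$ ($X_t \to Y_{t+1}$, $Y_t \to X_{t+1}$) and, per wave,
*correlational* paths $a$ (the within-wave association; residual at waves 2
and 3).  The cross-lagged paths are partial regressions: each wave-$(t+1)$
variable is regressed on both wave-$t$ variables.  `fit_clpm()` estimates
the paths by equationwise least squares on individual-level data — for a
saturated recursive path model this reproduces the maximum-likelihood point
estimates equation by equation — and computes cluster-robust (sandwich)
standard errors over families, because the two members of a twin pair are
not independent observations.

### ACE cross-lagged model

Each observed variable is the sum of three latent components,
$P = A + C + E$, and each component follows its own autoregressive
cross-lagged process across the three waves: a free 2×2 wave-1 covariance
block, a free 2×2 transmission matrix per interval (diagonal entries are
component stability paths, off-diagonal entries component cross-lagged
paths) and free 2×2 innovation covariance blocks at waves 2 and 3
(innovation cross-trait covariances carry the residual correlational
paths — they are retained because without them later-wave within-wave
associations could only arise through transmission, which the data need not
support; any of them can be fixed to 0 through the model specification).
Across twins, the components correlate $\rho_A = 1$ (MZ) or $0.5$ (DZ),
$\rho_C = 1$ and $\rho_E = 0$.  The DZ genetic correlation of 0.5 assumes
random mating; it is exposed as `rho_a_dz` for sensitivity analysis.  The
implied 12×12 covariance of a pair's observations is available in closed
form because transmission is strictly lower-triangular in time
(`implied_moments()`), and it is the single source of truth: the simulator
and the fitted likelihood are both validated against it.

The likelihood is full-information maximum likelihood: each row contributes
the multivariate-normal log-density of its observed subset, so pairs with
missing waves stay in the analysis.  With complete data the criterion
collapses to the covariance form computed from sufficient statistics; the
two code paths are algebraically identical and are tested against each
other.  Estimation maximizes the two-group deviance by BFGS from multiple
jittered starts around a method-of-moments initialization (a multivariate
Falconer decomposition of the observed moments projected onto the
autoregressive structure).  Fit is judged against the saturated two-group
means-and-covariances baseline via likelihood-ratio test and AIC; with
missing data the saturated maximum is found by an EM algorithm for the
multivariate normal.

### Decomposition of paths

Results are reported on the standardized scale (every observed variable
scaled to unit implied total variance).  The contribution of component $k$
to a path from source $S$ to target $T$ follows the path-tracing rule:
loading of the source on its $k$ component, times the latent $k$ path,
times the loading out to the standardized target, which equals
$c_k^{\mathrm{raw}} \cdot \mathrm{Var}(K_S) / (\mathrm{sd}_S\,
\mathrm{sd}_T)$.  Under this convention the three contributions sum exactly
to the total standardized path, and the total reproduces the phenotypic
CLPM projection up to terms of the order of the squared within-wave
correlation (small here); both identities are asserted by tests.  Percentage
shares are $100\,\beta_k / \beta_{\mathrm{total}}$.  When contributions
oppose in sign the shares are reported signed — they can then individually
leave $[0, 100]$ — and flagged; when the total path is numerically zero
($|\beta| < 10^{-6}$) shares are undefined and returned as `NA` rather than
0/0.

### Model reduction

Freely estimated twin SEMs of this size can be poorly conditioned,
especially where C variances are small.  `fit_correlated_factors()` fits
the unstructured alternative — each of the six variables decomposed into
A/C/E with free cross-variable correlation matrices per component,
parameterized by 6×6 Cholesky factors so the correlation matrices are
always valid — and `reduce_model()` fixes to zero every C cross-trait
parameter of the cross-lagged model whose corresponding shared-environment
correlation (rC) has a confidence interval covering zero at level `alpha`
(default 0.05).  C variances and C stability paths are always retained.
Every decision is logged in the returned specification.

### MZ-differences design

Within an MZ pair both A and C are identical, so within-pair difference
scores remove them by construction.  `fit_mzdiff_clpm()` fits the same
cross-lagged structure to the differences (one row per family, no
clustering needed).  A- or C-mediated cross-lags vanish in expectation
among difference scores, while E-mediated ones survive with their sign; the
concordance between significant difference-score paths and significant E
components from the ACE model is the design's corroboration.  Intercepts
are retained (difference means are near but not forced to zero, a
robustness guard against order-convention artifacts), and slopes are
reported both on the raw difference scale and standardized, since both
conventions circulate and neither is privileged.

## The synthetic cohort generator

The generator (`simulate_pairs()`) draws each component's wave-1 latent
vector for the two twins from one multivariate normal whose cross-twin
correlation is the component's zygosity coefficient, propagates through the
transmission matrices with cross-twin-correlated innovations, sums the
components, optionally injects sex and age effects, and applies wave-level
missingness last.  It emulates:

* continuous, standardized phenotypes arising from a latent A/C/E
  autoregressive cross-lagged structure;
* MZ and DZ pairs in equal numbers by default;
* sex and per-wave age effects to be residualized out (`residualize()`);
* per-twin wave-level retention of 1.00 / 0.62 / 0.82, matching the
  attrition of the motivating cohort (all twins observed at age 7, fewer at
  9, more again at 12).

It does *not* emulate ordinal questionnaire items (phenotypes are the
continuous composites that are actually analysed), assortative mating,
sibling interaction, sex-limitation, gene–environment interplay, or
selective (non-MCAR) attrition.  Recovery tests on these cohorts therefore
validate the estimators under the model's own assumptions; they cannot
detect biases that arise only when those assumptions fail in real data.

### Calibration of the shipped presets

Three presets ("general", "verbal", "nonverbal") encode the study
conditions of the three analyses (each cognitive measure paired with
emotional problems).  A preset fixes, on the standardized scale: the
per-wave A/C/E variance shares of each trait, the four stability and four
cross-lagged path totals, the A/C/E percentage share of every cross-lagged
path, and the three within-wave correlations.  `calibrate_ace_model()`
turns these targets into raw generating parameters exactly:

* observed variables get unit implied variance by construction (innovation
  variances are solved as the residual needed to hit each wave's variance
  share);
* cross-lagged raw paths are solved from the target contribution of each
  component (`c_k = beta_k / Var(K_S)`), so the decomposition shares are
  carried exactly;
* stability-path totals are allocated across components in proportion to
  the geometric mean of the source- and target-wave component variances — a
  neutral choice equivalent to giving all components the same transmitted
  fraction — with a feasibility cap: if a component's transmitted variance
  would exhaust its target at the next wave (which happens when a printed
  cross-lagged share loads on a component whose next-wave variance is 0.01
  or 0.02), its stability share is reduced so the innovation keeps at least
  10% of the target, and the remainder is redistributed;
* within-wave covariances are allocated across components in proportion to
  the geometric mean of the relevant variances (equal latent correlations);
* a fixed-point loop (exact to 10⁻¹²) aligns the internal path totals with
  the *phenotypic projection*, so that the phenotypic CLPM fitted to large
  simulated cohorts recovers the preset's stability/cross-lagged values —
  the three components transmit with different stabilities, so the
  projection differs from the sum of contributions by up to ~0.02 and the
  calibration absorbs that difference.

Values the presets need but that are not part of the published solution
were fixed once as plausible for residualized childhood cognition/emotion
composites and are not revisited: stability totals per preset (0.40–0.58,
cognition more stable than emotional problems), the age-9 h²/e² pair that
accompanies each printed age-9 c², within-wave correlations inside the
reported cross-sectional ranges, the A/E split of cross-lagged paths where
only one component's share is printed, and one rounding repair (a printed
variance triple summing to 1.01 has its e² reduced by 0.01).

## Numerical choices

* **Parameterization.** Covariance blocks via Cholesky factors: variances
  are sums of squares, so estimated proportions are bounded at zero (no
  negative variance components); transmission paths are unconstrained.
  Boundary solutions (a Cholesky diagonal pinned near zero) are listed in
  the fit object.
* **Optimizer.** BFGS, relative function tolerance 10⁻¹², restarted once at
  the incumbent; default 10 starts (method-of-moments start plus jitter;
  the start RNG is seeded independently of the caller's stream so fits are
  reproducible).  Convergence requires optimizer code 0 and a mean-deviance
  gradient sup-norm below 10⁻³ (about 10⁻⁵ per observation-parameter on
  cohort-sized data); nonconvergence is returned as a flagged result, and
  `fit_ace_clpm()` errors only if *no* start produces a usable optimum.
* **Non-PD proposals.** A parameter point whose implied covariance fails
  the Cholesky test contributes a deviance of 10¹² (log-likelihood −∞ at
  the user interface), keeping the optimizer inside the feasible region
  without exceptions.
* **Identification.** `check_identification()` verifies full column rank
  of the Jacobian of implied moments at the start point (the default
  57-parameter specification is identified: the two groups' 156 distinct
  moments over-determine it, with the no-lag-2-transmission restriction
  supplying the only structure).
* **Confidence intervals.** Delta method on the observed information
  (`se = "delta"`), matching the symmetric intervals conventional in this
  literature.  Near variance boundaries delta intervals are dubious; the
  decomposition flags such paths, and shares of near-zero totals are the
  main case where intervals should not be over-read.
* **Means.** Freed per variable, equated across twins and zygosity groups —
  residualized data have means near zero, but FIML with missing data needs
  the mean structure.

## Problem sizes used by the test suite

The shipped validation uses cohorts of 5,000 pairs per zygosity (about
double the motivating study) refitted over 20–30 seeds for recovery and
share targets, 200,000 pairs per zygosity for the simulator/closed-form
agreement check (entrywise tolerance 0.01), 200 replicates at 1,500 pairs
per zygosity for the likelihood-ratio null calibration against χ²(1), and
100 replicates of 1,000 MZ pairs for the difference-score sign check.

## Known limitations

* Percentage shares of *small* cross-lagged paths are ill-conditioned: the
  share divides by a total of order 0.04–0.07, so a finite-sample ML bias
  of a few thousandths in one contribution — the scale of bias the
  zero-boundary on small C variances induces at realistic cohort sizes —
  moves the share by ten points or more.  Shares of paths with totals
  around 0.1 are stable.  The decomposition's absolute contributions
  (`beta_A`, `beta_C`, `beta_E`) are the better-behaved quantities.
* Likelihoods are multivariate normal; ordinal or threshold measurement is
  out of scope.
* Missingness is handled as (M)CAR by FIML; informative attrition is not
  modelled.
* The design assumptions themselves (random mating, equal environments, no
  sibling interaction) are inputs, not testable outputs; `rho_a_dz` allows
  a simple sensitivity probe of the first.

## A minimal session

```{r, eval = FALSE}
library(twinlag)

model <- twin_preset("general")          # calibrated generating model
pairs <- simulate_pairs(model, n_mz = 2000, n_dz = 2000, seed = 1,
                        missingness = "wave", covariates = TRUE)
panel <- residualize(pairs, traits = model$traits)

fit_clpm(panel)                          # phenotypic paths, clustered SEs

cf <- fit_correlated_factors(panel, se = "delta")
spec <- reduce_model(ace_model_spec(), cf)      # drop obsolete C paths
fit <- fit_ace_clpm(panel, spec = spec, se = "delta")
decompose_paths(fit)                     # A/C/E contributions and shares
variance_components(fit)                 # univariate h2/c2/e2 per wave
lrt_vs_saturated(fit)                    # fit indices

fit_mzdiff_clpm(make_differences(panel)) # corroboration from MZ differences
```

The same pipeline, with stage artifacts, logging and a consolidated path
table, is available as `run_analysis()`.
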