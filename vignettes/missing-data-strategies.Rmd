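---
title: "Comparing missing-data strategies for longitudinal cost-effectiveness data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing missing-data strategies for longitudinal cost-effectiveness data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cemisim)
```

## Scope and design

`cemisim` is a simulation laboratory for one focused methodological
question: when longitudinal cost and utility data from a two-arm trial are
incomplete, does a likelihood-based mixed model need multiple imputation
first, and how do simpler alternatives (complete-case analysis, mean
imputation) and a joint total-cost/QALY model compare? The package is
organised as a pipeline of independently testable stages:

1. **`generate_complete_trial()`** — complete trials with the statistical
   signature of empirical economic-evaluation data;
2. **`calibrate_missingness()` / `impose_dropout()`** — monotone MAR
   dropout calibrated to a target missingness proportion;
3. **`run_strategy()`** — the six analysis strategies;
4. **`performance_table()`** — bias, RMSE and coverage with Monte Carlo
   standard errors;
5. **`ceac_curve()`** — parametric incremental-net-benefit probabilities.

## The data-generating model

Each trial draws, per subject: arm `trt ~ Bernoulli(0.52)`; age
`N(40 + 5 trt, 140)` clipped to `[18, 99]` years; male gender
`Bernoulli(0.52 + 0.40 trt)` (capped at 1, i.e. 0.92 in the intervention
arm). Baseline costs and utilities are gamma distributed with means linear
in age and gender and fixed dispersions, connected by a Gaussian copula.
Wave-1 outcomes are gamma around `baseline + arm effect + age/gender
terms`; waves 2–4 add compound-symmetric normal perturbations around the
wave-1 value. Utilities are truncated into `[0, 1]` and costs floored at 0.

Two parameterization choices deserve comment, because the description the
design was taken from is not fully self-consistent:

* **Identity-link gamma.** The cost means live in the hundreds of euros;
  a logit link would saturate them at 1. We therefore read the linear
  predictors as means on the natural scale, with "variance" interpreted as
  a gamma dispersion `phi` so that `Var = phi * mean^2`. This reproduces
  both the intended magnitudes and the right skew (shape `1/phi`, about
  6.7 for costs).
* **Follow-up wave noise.** The stated follow-up "variances" (0.1 costs,
  0.005 utilities) are likewise treated as relative: the perturbation SD is
  `sqrt(v)` times the subject's wave-1 value. Taken as absolute variances
  they would make waves 2–4 copies of wave 1 to within cents. Under the
  relative reading the complete-data sampling SD of the estimated total
  cost difference at n = 600 comes out near the RMSE magnitudes the design
  targets (the acceptance runs measure ~150 EUR).

Consequences worth knowing:

* The **marginal** Pearson correlation between baseline costs and utilities
  is *positive* (~0.37), because age drives both means upward; the stated
  −0.5 is the copula correlation *conditional on covariates*. The package
  tests the partial correlation after regressing out age and gender
  (−0.48 at n = 50,000; the small attenuation is the usual price of
  non-Gaussian margins under a Gaussian copula).
* Follow-up correlations are compound-symmetric *within* construction
  groups: `corr(T1, Tj)` (~0.86 for costs) differs slightly from
  `corr(Tj, Tk), j,k >= 2` (~0.92), an unavoidable feature of generating
  waves 2–4 around wave 1. Utilities behave analogously at higher levels.
* Because every conditional mean is linear in `(trt, baseline, age,
  gender)` and truncation essentially never binds at the default
  parameters, the true estimands are exactly `4 x 62.5 = 250` EUR and
  `0.04` QALY; `check_calibration()` verifies this on demand against a
  200,000-subject trial.

## Dropout model and calibration

Dropout is a per-wave Bernoulli hazard on the logit scale in baseline age,
gender, baseline cost and utility, and arm — never in follow-up outcomes,
so the mechanism is MAR by construction (a permutation test in the suite
confirms the draws ignore follow-up values). Applied sequentially over
waves it yields monotone patterns with costs and utilities missing jointly.

The original tweaked coefficients are not public, so the package ships the
calibration instead of constants: covariate effects default to a log-odds
of 0.2 per SD of each predictor (signs: +age, +gender, +cT0, −uT0 — the
sicker and costlier drop out more), the arm coefficient is
`log(arm_odds_multiplier)`, and the intercept is root-found so the
*expected* proportion of subjects with any missing follow-up,
`mean(1 - (1 - pi_i)^4)` over a generated pilot population (default
50,000), equals the target. Because that expectation is analytic the
calibration is deterministic given the pilot seed; realized proportions in
finite trials then scatter binomially around the target. "X% missing" is
read as the share of *subjects* with at least one missing wave; a
wave-level definition would need different intercepts, which users can
supply directly through `missing_spec()`.

## The six strategies

**Mixed-model family.** `fit_llm_outcome()` fits, per outcome, a
random-intercept model by full ML (`lme4::lmer`, `REML = FALSE`) with
categorical wave effects and wave interactions with arm, baseline, age and
gender; omitting the global intercept and using per-wave interaction slopes
is an equivalent parameterization of the usual main-effect form, and makes
the per-wave adjusted contrasts directly readable with their covariance
block. Dropping rows with missing outcomes gives the observed-data
likelihood, valid under MAR. Totals: ΔC sums the four contrasts; ΔQ uses
**rectangle AUC weights** (0.25 per wave). Rectangle weights are the only
convention under which four per-wave utility differences of 0.04 integrate
to the stated true 0.04 QALY; the trapezoid variant (which would give
0.035) is available via `auc = "trapezoid"`.

**SUR family.** `aggregate_totals()` builds per-subject totals;
`fit_sur()` estimates the two-equation system by two-step feasible GLS with
the residual covariance estimated from OLS residuals (divided by n). The
normal equations are Jacobi-scaled before solving — costs (~10^3) and QALYs
(~10^-1) otherwise produce condition numbers near machine precision. With
identical regressor matrices FGLS collapses to per-equation OLS exactly;
the suite asserts this identity and checks the general case against an
explicit Kronecker-product oracle.

**Imputation.** `mean_impute()` is the naive reference: available-case
column means, pooled over arms ("unconditional"; an arm-stratified switch
exists). `mice_pmm()` is a self-contained chained-equations imputer with
type-1 predictive mean matching: within each arm stratum, the imputation
model for a variable is linear in age, gender, both baselines and the other
follow-up columns; regression parameters are drawn from their approximate
posterior (normal/inverse-chi-square), missing cases are matched to the
`knn = 5` observed cases nearest by predicted mean, and one donor's
observed value is drawn. Donor values guarantee range preservation
(utilities stay in `[0, 1]`, costs nonnegative). Monotone patterns are
completed in a single visit-ordered sweep (wave 1 → 4, cost before
utility), which is proper under monotone dropout; non-monotone inputs fall
back to a 10-iteration chain. The number of imputations follows
`choose_m()`: 10 up to 25% missing subjects, 20 at 50%, keeping the
loss-of-efficiency proxy `proportion/m` below 0.05. Pooling uses Rubin's
rules with Barnard–Rubin small-sample degrees of freedom (the source design
does not state its df rule; the large-sample normal CI is the `df_com =
Inf` special case).

**Covariance of (ΔC, ΔQ).** The SUR family provides it from the joint fit
(Rubin-pooled within + `(1 + 1/m)` between for MI-SUR). The mixed-model
family fits two separate univariate models, so no internal covariance
exists; estimates carry `cov_available = FALSE` and the CEAC treats it as
zero. At `lambda = 0` the acceptability probability depends only on ΔC and
its variance, which is why published worked examples at that threshold are
reproducible regardless.

## Performance measures and replication sizing

Empirical bias, RMSE and coverage follow the standard simulation-study
definitions, with MCSEs `SD/sqrt(n)`, delta-method on the MSE
(jackknife-cross-checked in the suite), and binomial respectively. Every
table build asserts `RMSE^2 = EB^2 + (n-1)/n Var` to machine precision.
Coverage is flagged poor when `|CR - 0.95| > 1.96 MCSE(CR)` — a concrete
operationalization of "more than Monte Carlo error from nominal".
`required_nsim(0.95, 0.5)` returns the 1900 replications that motivated the
original 2000; the guard `ceiling(x - 1e-8)` avoids the floating-point
overshoot that would otherwise return 1901.

## Seeds and determinism

Every generator takes an explicit seed and restores the caller's RNG state.
`run_scenario()` mixes `(master_seed, replication)` through an LCG-style
integer hash into well-separated substream keys, so (i) reruns are
byte-identical, (ii) replication r is identical whether run alone or in a
batch, and (iii) adjacent master seeds yield effectively independent
streams (a plain `master + r` scheme would share almost all replications
between seeds 1 and 2). MI-LLM and MI-SUR within a replication share one
imputation seed, hence analyse identical completed datasets — mirroring the
design in which both strategies consumed the same imputations.

## Problem sizes

The shipped tests and the acceptance script run at sizes chosen to keep a
single-CPU run in minutes while leaving the Monte Carlo error small enough
to be informative: 500 replications of n = 600 for coverage comparisons
(binomial MCSE ~1 percentage point), one 200,000-subject trial for estimand
recovery (SE ~8 EUR for costs), 50,000-subject samples for distributional
checks, and a 40-subject fixture for the brute-force ML oracle. The full
2000-replication design is reproducible by raising `n_sims`; coverage
comparisons in the suite account for the Monte Carlo error on *both* sides
(ours at 500 replications, published values at 2000).

## What the generator does and does not emulate

It reproduces: right-skewed, baseline-anchored costs; utilities bounded in
`[0, 1]`; negative conditional cost-utility correlation; strong serial
correlation; covariate-driven monotone MAR dropout with differential
dropout by arm. It does **not** emulate: item-level (component) costs and
non-monotone missingness; MNAR mechanisms; unequal visit intervals;
heteroskedastic measurement regimes beyond the mean-proportional gamma
noise. Conclusions from passing tests therefore speak to aggregate-level
monotone MAR settings; real trials with intermittent item-level gaps need
the chained (non-monotone) imputation path and, ideally, sensitivity
analyses outside this package's scope.

## Known limitations

* The mixed models assume normal errors while costs are gamma; at n = 600
  the Wald CIs for the cost contrast show mild undercoverage (~0.948
  measured for the complete-data SUR at 2000 replications) — a property of
  the methods under study, not a defect of the harness.
* The FGLS covariance is the large-sample one (no small-sample df
  correction), matching common software defaults.
* PMM with a posterior parameter draw is "proper enough" in practice but
  is not a fully Bayesian imputation; with very small donor pools its
  between-imputation variance can be optimistic. The imputer refuses to
  run when a stratum has fewer observed cases than `knn`.
* `fit_llm_outcome()` requires every wave to retain some observed data
  (true in all shipped scenarios; 100% dropout at a wave would need a
  reduced wave set).
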