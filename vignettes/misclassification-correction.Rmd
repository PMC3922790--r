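---
title: "Correcting case-control odds ratios for exposure misclassification"
author: "bayesmisclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting case-control odds ratios for exposure misclassification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Case-control studies of childhood outcomes often rely on a caregiver's
retrospective report of an exposure — here, household use of a pesticide
product during pregnancy, recalled on average several years later. Recall is
imperfect, and its accuracy may differ between mothers of cases and mothers
of controls (recall bias). Two probabilities summarize the measurement
process for a binary exposure, each possibly different for cases and
controls:

* **sensitivity (Se)** — the probability that a truly exposed mother reports
  the exposure;
* **false-positive probability (FPP = 1 − specificity)** — the probability
  that a truly unexposed mother reports it anyway.

Non-differential error (equal Se and FPP in both groups) attenuates the odds
ratio toward the null; differential error can bias it in either direction.
When no validation study pins down Se and FPP, the honest analysis reports
the corrected odds ratio across a grid of plausible measurement scenarios
rather than a single "corrected" number.

## The joint model

Let $Y_i$ be case status, $C_i$ the covariate vector, $X_i$ the latent true
exposure and $X_i^*$ the reported exposure. The correction jointly estimates
three linked models:

1. **Exposure model** $\;\mathrm{logit}\,P(X_i = 1 \mid C_i) = C_i'\alpha$,
   with tight $N(0,1)$ priors on $\alpha$;
2. **Measurement model**
   $\;P(X_i^* = 1 \mid X_i, Y_i) = \mathrm{Se}_{Y_i}^{X_i}\,
   \mathrm{FPP}_{Y_i}^{\,1-X_i}$, with Se and FPP fixed known constants per
   scenario (the *certain misclassification* assumption: the scenario is a
   point mass, and uncertainty about it is explored by sweeping scenarios,
   not by a hyperprior);
3. **Outcome model** $\;\mathrm{logit}\,P(Y_i = 1 \mid X_i, C_i) =
   \beta_0 + \beta_x X_i + C_i'\beta_c$, with user-chosen normal priors
   (vague $N(0,10)$ by default); $e^{\beta_x}$ is the corrected odds ratio.

The exposure-model design equals the outcome-model design minus the exposure
term; both condition on the full covariate set, including the matching
factors. The latent exposure has the closed-form full conditional

$$P(X_i = 1 \mid X_i^*, Y_i, C_i) \propto
  P(X_i^* \mid X_i = 1, Y_i)\, P(Y_i \mid X_i = 1, C_i)\, P(X_i = 1 \mid C_i),$$

normalized against the $X_i = 0$ branch
(`latent_exposure_conditional()`). Identifiability requires the report to
carry information, i.e. Se > FPP within each group; scenarios violating this
are rejected by default (`misclass_scenario(allow_nonidentifiable = TRUE)`
downgrades the guard to a warning for exploratory use).

Setting Se = 1 and FPP = 0 pins the latent exposure to the report, and the
joint model reduces exactly to the naive Bayesian logistic model — a
property the test suite exercises as an end-to-end check.

## Sampling

`run_mcmc()` runs a data-augmentation MCMC: each iteration redraws every
record's latent exposure from its exact full conditional (a Gibbs step,
independent across records given the coefficients), then updates the
exposure-model and outcome-model coefficients by componentwise random-walk
Metropolis. Step sizes adapt by a Robbins-Monro rule toward an acceptance
rate of 0.38 during burn-in only, so the post-burn-in kernel is a fixed,
valid Metropolis transition. The coefficient kernel is an internal choice:
any transition preserving the conditional posterior would do; the latent
step is always exact Gibbs. The sweep is implemented in C++ (Rcpp) with R's
RNG, so runs are reproducible bit-exactly from the configuration seeds.

Defaults (`mcmc_config()`): 3 chains of 15,000 iterations including a
2,000-iteration burn-in, no thinning, one seed per chain derived as `seed`,
`seed + 1`, ... (identical chain seeds are rejected). Convergence is
assessed by split-chain R-hat with threshold 1.1 and a variogram-based
effective sample size; a run exceeding the threshold errors (or warns,
configurable) carrying the per-coefficient report. Chains are pooled after
burn-in; the corrected odds ratio is summarized by the median and the 2.5th
and 97.5th percentiles of the pooled $\beta_x$ draws, computed on the log
scale and then exponentiated (quantiles commute with monotone
transformations, so the order of pooling and exponentiation matters only
through this documented choice).

MCMC-free alternatives exist for the naive estimators: the frequentist
models are ordinary `glm()` fits with Wald intervals (profile-likelihood
intervals behind `ci_method = "profile"`), and the crude odds ratio is the
closed-form cross product with the standard log-scale variance
$1/a + 1/b + 1/c + 1/d$ (Haldane 0.5 correction when a single cell is zero;
a zero margin is an error).

## Scenario grids

`build_grid()` crosses baseline sensitivities (default 0.70-1.00) and
false-positive probabilities (default 0.00-0.20) with the four
differential-recall groups: (1) accuracy favoring controls, (2)
non-differential, (3) accuracy favoring cases in both parameters, (4)
sensitivity favoring cases only. The baseline applies to the less accurate
group and the favored group's parameter is shifted up by a configurable
offset (default 0.10); shifted probabilities leaving $[0,1]$, or scenarios
failing the identifiability guard, are dropped with a message. Scenarios are
independent, so `run_grid()` isolates per-scenario failures and reproduces
identically under the same seeds regardless of execution order.

A known and intended behavior of certain-misclassification models is
hypersensitivity to the FPP when it approaches the *reported* exposure
prevalence: if the assumed FPP among controls nearly equals their reported
prevalence, the model attributes almost all control reports to false
positives, the implied true prevalence collapses toward zero and the
posterior OR explodes (or collapses, symmetrically, for the case group).
Grid summaries should therefore be read as a sensitivity analysis, not as a
set of competing point estimates.

## The synthetic cohort generator

No individual-level data ship with the package; every analysis runs on
synthetic cohorts from `generate_cohort()`. The generator simulates a source
population (default 50 times the requested sample), draws true exposure from
a logistic model given covariates, the outcome from a logistic model given
true exposure and covariates, samples the requested number of cases, and
frequency-matches controls by sampling within sex-by-region strata in
proportion to the realized case distribution (largest-remainder allocation;
a stratum that cannot supply its allocation is an explicit error naming the
shortfall). Reported exposure is then generated by the measurement model,
and exposure timing by a one-parameter Markov run over seven ordered windows
(three months pre-conception, three trimesters, three post-natal years): an
anchor window is drawn uniformly among the four prenatal windows and the
flag propagates outward, each further step succeeding with probability
`window_agreement` (default 0.9), so adjacent windows are highly correlated.
Use is labelled *consistent* when all three trimester flags are set and
*occasional* otherwise. The generator emits complete data; an MCAR injector
(`inject_missing()`) exists to exercise complete-case filtering, whose
dropped-record count travels with every design matrix.

`charge_like_config()` fixes the emulation target: 587 cases / 356 controls;
education split near 41/15/44% in cases; ~84% male; interview age normal
(mean 3.7 y, SD 0.8) truncated to 2-5 years and centered; parity a truncated
geometric on 1-6; five regions; pet ownership the dominant exposure
predictor. True exposure prevalence is set near 8% so that under the default
non-differential scenario (Se 0.85, FPP 0.05 — mid-range plausible values)
the *reported* prevalence lands near the published 12% (cases) and 11%
(controls); the exposure-model intercept (-3.25) was calibrated once against
those reported margins. The true exposure log odds ratio defaults to
log(1.3). Window indicators cover the first three post-natal years — the
wider of the two time spans the source material mentions — so window
analyses can contrast prenatal against all early-life reports.

What the generator does *not* emulate: the real study's missingness
mechanism (its generator is unknown; the injector is MCAR only), informative
prior tables (shipped as a user-editable JSON hook, not values), seasonal or
co-exposure structure, and any genetic susceptibility subgroups. Passing
tests on synthetic cohorts therefore validate the estimators' behavior under
a known generative process, not the published study's specific numbers,
which require the original individual-level data.

## Design choices where the design was open

* **Consistency-stratified models** default to two separate fits, each
  excluding the other exposed stratum; a single three-level-exposure fit is
  available (`joint = TRUE`) and agrees with the separate fits at large n.
* **Latent updates and record order.** Records are updated in index order
  from one RNG stream, so permuting rows changes the realized draws;
  order-invariance holds in distribution (tested within Monte Carlo
  tolerance) rather than bit-exactly. Bit-exact reproducibility is per
  configuration: same cohort, same seeds, same draws.
* **Measurement priors are point masses only.** Uncertain (e.g. Beta)
  Se/FPP priors and correlated Se/FPP priors are out of scope; scenario
  sweeps are the supported way to represent measurement uncertainty.
* **Rounding.** Publication-style tables round ORs, limits and limit ratios
  to two significant figures (`display_table()`, `format_or()`); machine
  CSVs always keep full precision.
* **Problem sizes.** The analysis scripts use the full 3 x 15,000
  configuration for the headline fits and scale the scenario grid and the
  replicated simulations down (3 x 3,000 per grid point; 2 x 1,500 per
  recovery replicate, 50 replicates at 1,000 cases / 1,000 controls) — sizes
  chosen so the whole pipeline runs on a laptop core in minutes while
  keeping the Monte Carlo error of each reported summary an order of
  magnitude below the effects being summarized. The full-scale settings are
  one argument away (`mcmc_config()`).

## Known limitations

* At realistic prevalence (~10%) and moderate error (Se 0.85, FPP 0.05),
  the corrected posterior median is essentially unbiased for the true log OR
  (the package's recovery simulation: mean 0.75-0.79 against a true 0.693 at
  n = 2,000, and centered at larger n) and its 95% credible interval is
  honest, but the correction trades bias for variance: its replicate spread
  (~0.25) is comparable to the naive estimator's attenuation bias, so in
  roughly a third of replicates at n = 2,000 the *biased* naive estimate
  lands closer to the truth by luck. The correction's advantage is
  systematic, not per-dataset, and grows with sample size.
* Corrected ORs react explosively when an assumed FPP approaches the
  reported prevalence of the relevant group (see the grid section); extreme
  grid cells signal near-non-identifiability, not evidence.
* The exposure model's tight N(0,1) priors mildly shrink the exposure-model
  intercept toward 0; at the emulated prevalence this has negligible effect
  on the corrected OR (checked against vague exposure priors in
  development), but for very rare exposures a user may prefer a wider
  intercept prior via `joint_model_spec(exposure_priors = ...)`.
* The latent-exposure Gibbs step mixes slowly when Se - FPP is small;
  scenarios near the identifiability boundary need longer chains, and the
  split-R-hat gate is the intended guard.
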