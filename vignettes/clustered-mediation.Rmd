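---
title: "Mediation analysis with many mediators in family-clustered cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mediation analysis with many mediators in family-clustered cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustmed)
```

## The scientific question

APOE is the single strongest common genetic factor for late-life cognition,
and a central actor in lipid metabolism. clustmed implements a
regression-based causal mediation analysis that asks how much of the effect
of carrying the protective APOE2 genotype (e2e2 or e2e3, versus the e3e3
reference; e4 carriers excluded) on digital Clock Drawing Test (CDT)
completion times is transmitted through circulating lipid species, in
cohorts where participants are nested in families. Three outcomes are
analysed separately: think-time (pen-in-air planning time), ink-time
(drawing time) and their exact sum, total-time, all in seconds.

## Model and decomposition

For exposure $A \in \{0,1\}$, mediators $M_1,\dots,M_K$ (log-transformed,
z-scored lipid abundances), confounders $C$ (age at enrollment, sex, years
of education, BMI, lipid-lowering medication use, and a generation indicator
defined by birth year > 1935) and an outcome $Y$, two sets of marginal
linear models are fit on the same analysis sample:

* one *mediator regression* per lipid: $E[M_k] = \alpha_{0k} + \alpha_k A +
  \gamma_k' C$;
* one *outcome regression* per CDT time: $E[Y] = \theta_0 + \theta A +
  \sum_k \beta_k M_k + \gamma' C$.

The product method combines them: the indirect effect through mediator $k$
is $\delta_k = \alpha_k \beta_k$, the combined indirect effect is
$\Delta = \sum_k \delta_k$, the direct effect is $\theta$, the total effect
is $\tau = \theta + \Delta$, and the mediated proportion is $\Delta/\tau$.
Negative effects are protective (faster test completion). No
exposure–mediator interactions are modelled, and identification rests on
the usual sequential-ignorability assumptions plus the measured temporal
ordering (genotype at birth, lipids at the first visit, CDT at the second).

Because families share genes and environment, all models are estimated by
Gaussian identity-link GEE with an exchangeable working correlation over
family clusters. Coefficients solve the weighted estimating equations;
the working correlation is re-estimated each iteration by the moment
(Pearson-residual pair) estimator with the scale using the bias-corrected
$n-p$ denominator; inference uses cluster-robust sandwich standard errors,
so it is valid even when the exchangeable structure is wrong. Setting
`engine = "ols"` switches to an independence working correlation, whose
point estimates are ordinary least squares while standard errors remain
cluster-robust; with every family of size one the two engines coincide
exactly, which the tests exploit as an oracle.

## Confidence intervals

All reported quantities get Efron percentile intervals from a cluster
bootstrap: families are resampled with replacement (the resampled copies
treated as distinct clusters), the entire estimation is re-run per
replicate, and the 2.5/97.5 empirical percentiles (interpolated, the
`type = 7` convention of `stats::quantile`) form the 95% interval; the
study convention is 1500 replicates. Resampling whole families rather than
individuals preserves the within-family correlation the GEE accounts for;
`resample_unit = "individual"` exposes the alternative for sensitivity
checks. Mediator standardization is treated as a fixed preprocessing step
and is not redone inside replicates (flag `restandardize` reverses this).
Significance is read off as "the interval excludes zero"; the mediated
proportion, a ratio whose bootstrap distribution crosses zero whenever the
total effect is small, carries no significance flag, and a total effect
below 0.1 s flags the proportion as numerically unstable. Replicates that
fail to converge are dropped and counted; more than 1% failures aborts the
analysis rather than silently reporting biased intervals.

The mediated proportion's interval is the percentile interval of the
replicate-wise ratios, untruncated — consistent with published analyses of
this design, whose proportion intervals are very wide (e.g. 27% with a
−13% to 82% interval).

## Secondary and sensitivity analyses

The secondary analysis applies backward stepwise deletion of mediators in
each outcome model, scored by AIC under the independence Gaussian
likelihood (`stats::lm` + `stats::AIC`) — the convention of standard
stepwise tooling, since GEE defines no likelihood. Only mediators are
eligible; exposure and confounders are forced. Ties are broken toward the
mediator listed first, so selection is deterministic, and the step trace
(AIC before/after each deletion) is part of the output. The mediation
analysis is then re-run on the retained set; selection happens once, on the
full sample, and the retained set is held fixed across bootstrap
replicates. The sensitivity analysis instead drops lipid-lowering
medication use from the confounders of *both* model sets and re-runs
everything.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure the analysis assumes, with every
parameter open to the user and defaults chosen to resemble the motivating
cohort: ~350 families of 1–6 members (≈1200 participants), exposure
prevalence 240/1228, 24 mediators, outcome noise SDs of 8 s (think) and 4 s
(ink), within-family correlation 0.3, and direct/combined-indirect effects
of about −1.9/−0.89 s (think) and −0.98/−0.17 s (ink). Confounders follow
fixed simple distributions (age ~ N(64, 8²), sex ~ Bernoulli(0.57),
education rounded N(13.5, 3²) clipped to 6–20, BMI ~ N(27, 4.2²), birth
year uniform 1915–1955); medication use depends on the exposure (32% vs
18%), creating a genuine confounding path when its outcome effects are
nonzero. Family correlation is induced exactly as exchangeable by a shared
Gaussian family intercept with variance $\rho\sigma^2$ plus individual
noise with variance $(1-\rho)\sigma^2$. Raw mediators are the exponential
of a latent linear log-abundance, hence strictly positive; think and ink
times are linear in exposure, latent log-mediators and confounders, and
total-time is their exact row-wise sum.

One design choice deserves a note: the generator defines the true indirect
effects as the config products $\alpha_k \beta_k$, with outcomes generated
from the *unstandardized* latent log-mediators. The product of the
exposure→mediator and mediator→outcome coefficients is invariant to affine
rescaling of the mediator, so these truths are exact on whatever scale the
pipeline standardizes to — which keeps truth values clean constants instead
of sample-dependent quantities — while the truth object also reports the
sample-standardized components for comparison with individual coefficient
estimates. What the generator does *not* emulate: lipid–lipid partial
correlation (independent given exposure and confounders by default, though
a correlation matrix can be supplied), non-Gaussian or skewed outcome
noise, missing data, and floor effects near zero seconds (simulated times
are unbounded below, so extreme noise draws can be negative). Passing tests
therefore validate the estimator under its own assumptions, not robustness
to real-data pathologies.

## Numerical conventions

* GEE convergence: max absolute coefficient change < 1e−8, at most 100
  iterations; non-convergence is an error, never silently reported.
* Working correlation clamped to its valid range
  $(-1/(\max n_i - 1),\, 1)$; with only singleton clusters it is 0.
* Mediator standardization uses the natural log and the $n-1$ sample SD;
  both choices are irrelevant to the effect estimates (z-scores are scale-
  and base-invariant) and fixed for reproducibility.
* Ambiguous APOE diplotypes (heterozygous at both SNPs) and genotype pairs
  forcing the undefined rs7412=T/rs429358=C haplotype raise distinct
  errors rather than being guessed, because the e4 exclusion makes a wrong
  guess consequential.
* Standardization statistics are always computed on the analysis sample,
  i.e. after the e4 and completeness exclusions.
* All randomness flows from explicit integer seeds; the bootstrap draws its
  resampling indices up-front so results do not depend on evaluation order.

## Validation strategy and problem sizes

The test suite validates the pipeline in layers: exact identities
(decomposition arithmetic; product ≡ difference method under least squares
to 1e−8; singleton-cluster GEE ≡ OLS; balanced intercept-only fit ≡ grand
mean), cross-checks against independent estimators (`nlme::gls` with
compound symmetry), and frequentist calibration on synthetic cohorts:
parameter recovery over 200 cohorts of 300 and 600 size-4 families,
percentile-CI coverage of the total effect over 300 cohorts of 150 families
with 200 bootstrap replicates each, a type-I error study of the
CI-excludes-zero rule under the null on the same design, and a selection
study of 40 cohorts with 2 signal and 4 noise mediators. These sizes keep
Monte-Carlo error well inside the asserted bands while remaining
routine-desktop work; the full 1500-replicate bootstrap is the recommended
setting for real analyses.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_cohort(sim_config(n_families = 350, n_mediators = 24,
                                  seed = 1))
d <- build_analysis_sample(sim$cohort,
                           mediators = sim$truth$mediators)
d <- preprocess_mediators(d, sim$truth$mediators)
fit <- medgee(d, outcome = "think_time", mediators = sim$truth$mediators)
fit
boot <- boot_medgee(fit, reps = 1500, seed = 2)
boot
plot(fit, boot = boot)
```

Or end to end, with all three outcomes, from a cohort CSV:

```{r pipeline, eval = FALSE}
cfg <- run_config("cohort.csv", mediators = sim$truth$mediators,
                  mode = "primary", reps = 1500, seed = 1)
run <- run_clustmed(cfg, out_dir = "run-primary")
```

## Known limitations

* Point estimation via GEE assumes the mean models are correct; the robust
  variance protects the standard errors, not the estimates, against
  working-correlation misspecification.
* The mediated proportion is unstable whenever the total effect is near
  zero; the instability flag and the untruncated bootstrap interval make
  this visible rather than hiding it.
* Backward stepwise AIC is a heuristic: it need not find the best subset,
  and post-selection inference is not corrected — the secondary analysis
  inherits the same caveat as the published design it mirrors.
* Complete-case analysis only; no imputation.
* Sequential ignorability is untestable; since genotype is fixed at birth,
  baseline covariates may be post-exposure, which complicates the causal
  reading of the adjusted estimates.
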