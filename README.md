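# clustmed

Causal mediation analysis with many continuous mediators in
family-clustered cohorts: how much of the effect of carrying the protective
**APOE2** genotype (e2e2/e2e3 vs the e3e3 reference; e4 carriers excluded)
on digital Clock Drawing Test (CDT) times — think-time, ink-time and their
sum, total-time, in seconds — is transmitted through circulating lipid
species, when participants are nested in families.

For whom: biostatisticians and genetic-epidemiology analysts running
regression-based mediation on clustered cohort data, and methodologists who
want a fully simulatable testbed for that design.

## The method

For exposure *A* ∈ {0,1}, mediators *M₁…M_K* (log-transformed, z-scored
lipid abundances), confounders *C* (age at enrollment, sex, education, BMI,
lipid-lowering medication use, generation indicator) and outcome *Y*:

* mediator regressions: E[*M_k*] = α₀ₖ + αₖ·A + γₖ'C, one per lipid;
* outcome regression: E[*Y*] = θ₀ + θ·A + Σₖ βₖ·Mₖ + γ'C.

Both are fit by Gaussian GEE with an **exchangeable working correlation**
over families and cluster-robust sandwich standard errors. The product
method combines them:

* indirect effect through mediator *k*: δₖ = αₖ·βₖ (δₖ < 0 is protective —
  the pathway shortens test time);
* combined indirect effect: Δ = Σₖ δₖ;
* direct effect: θ; total effect: τ = θ + Δ; mediated proportion: Δ/τ.

95% confidence intervals are Efron percentile intervals from a **family
bootstrap** (resample families with replacement, re-run the whole
estimation per replicate; 1500 replicates by convention). A secondary
analysis selects mediators by backward stepwise AIC in the outcome model
and re-runs the mediation on the retained set; a sensitivity analysis drops
the medication covariate from both model sets. A synthetic cohort
generator with known truth (`simulate_cohort()`) backs the validation
suite. The APOE group itself can be derived from unphased rs7412/rs429358
genotypes, with ambiguous diplotypes refused rather than guessed.

## Worked example

```r
library(clustmed)

sim <- simulate_cohort(sim_config(seed = 1))   # ~1200 people, 24 mediators
d   <- build_analysis_sample(sim$cohort, mediators = sim$truth$mediators)
d   <- preprocess_mediators(d, sim$truth$mediators)

fit <- medgee(d, outcome = "think_time", mediators = sim$truth$mediators)
fit
#> Causal mediation analysis (gee engine): think_time
#>   24 mediators, 1209 participants in 350 families
#>   Direct effect                -2.119 s
#>   Combined indirect effect     -1.148 s
#>   Total effect                 -3.267 s
#>   Mediated proportion             35%

boot <- boot_medgee(fit, reps = 1500, seed = 2)
boot
#> Family bootstrap (1500 replicates, 95% percentile CIs) for think_time
#>           quantity estimate ci_low ci_high significant
#>             direct   -2.119 -3.296  -0.885        TRUE
#>  combined_indirect   -1.148 -1.736  -0.523        TRUE
#>              total   -3.267 -4.407  -2.118        TRUE
#>      prop_mediated    0.351  0.157   0.623          NA
```

Read: APOE2 carriers complete the planning phase 3.27 s faster in this
simulated cohort; 1.15 s of that (35%) flows through the lipid pathways,
and the generator's true values (direct −1.9 s, combined indirect −0.89 s)
sit inside the intervals. `plot(fit, boot = boot)` draws the per-mediator
forest plot. The full pipeline — genotype exclusions, preprocessing, all
three outcomes, secondary/sensitivity modes, CSV/JSON reports — is
`run_clustmed(run_config(...), out_dir = ...)`, also reachable from a
shell via `inst/scripts/clustmed simulate|run`.

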