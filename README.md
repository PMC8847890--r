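# cocoaferm

Combinatorial kinetic modelling of cocoa bean fermentation.

Cocoa bean fermentation is driven by a three-phase microbial succession —
yeasts (Y) converting glucose and fructose to ethanol, lactic acid bacteria
(LAB) producing lactic and acetic acid, then acetic acid bacteria (AAB)
oxidising ethanol and lactate to acetate until product toxicity collapses
the populations. `cocoaferm` is for researchers who want to test *which
biochemical mechanisms* are needed to describe observed fermentation time
series, and whether fitted kinetic parameters carry the signature of
process features such as cultivar, fermentation method or temperature
control.

The package provides:

* **32 ODE model variants** over the states
  `Glc, Fru, EtOH, LA, Ac, Y, LAB, AAB`: a 24-parameter baseline
  (Monod/Contois growth $v_1..v_5$, Chick–Watson mortality
  $v_6 = k_Y[\mathrm{Y}][\mathrm{EtOH}]$,
  $v_7 = k_{LAB}[\mathrm{LAB}][\mathrm{LA}]$,
  $v_8 = k_{AAB}[\mathrm{AAB}][\mathrm{Ac}]^2$, and yield coefficients
  $Y_{a|b}$), extended by any subset of five mechanisms — M1 product
  decay, M2 fructose use by LAB, M3 acetate production by yeast, M4
  lactate use by yeast, M5 acetate over-oxidation by AAB — for 24–43 free
  parameters per variant (`enumerate_variants()`, `build_variant()`,
  `simulate_variant()`).
* **Bayesian fitting** of any variant to max-scaled trial data under
  truncated $N(0.5, 0.3)$ parameter priors and a half-Cauchy noise prior,
  with a mode-seeded, tempered differential-evolution MCMC sampler in C,
  rank-normalised split-R̂ / bulk- and tail-ESS diagnostics, and the
  strict "successful fit" verdict (R̂ < 1.05, ESS > 100, mean ESS ratio >
  12.5%, default priors only) with a single doubled-length rerun on ESS
  failure (`fit_variant()`, `check_convergence()`, `posterior_predict()`).
* **Variant scoring** across a dataset collection: in-package PSIS-LOO
  with Pareto-k diagnostics, pseudo-BMA weights, mean BMA weight, observed
  and expected success rates (`psis_loo()`, `pseudo_bma_weights()`,
  `compute_osr()`, `compute_esr()`, `assessment_table()`).
* **Feature classification** from posterior draws: per-chain joint 95%-CI
  filtering, parameter subgroups (growth rates, mortality rates, yields,
  Y/LAB/AAB-related), mean-centred unscaled PCA, and pairwise squared
  Mahalanobis separation of feature classes on PC1/PC2 with its median
  $\tilde D_M$ (`filter_ci_draws()`, `subset_params()`, `run_pca()`,
  `pairwise_mahalanobis()`).
* **A synthetic-trial generator** emulating literature fermentation
  datasets (6–17 observations over ~160 h, three-phase succession,
  Gaussian noise on the max-scaled space, metadata features), including
  labelled multi-class cohorts for classification experiments
  (`generate_trial()`, `generate_cohort()`).

## Worked example

```r
library(cocoaferm)

trial <- generate_trial(generator_config(variant = "MI(0)", seed = 42,
                                         n_timepoints = 12, noise_sd = 0.03))
trial
#> <ferm_dataset> syn_MI0_s42 - 12 time points over 160 h

scaled <- max_scale(trial)
fit <- fit_variant("MI(0)", scaled,
                   sampler = sampler_config(chains = 4, iter = 60000,
                                            warmup = 20000, thin = 40,
                                            temps = 1, seed = 1,
                                            rerun_on_ess_failure = FALSE))
fit
#> <ferm_fit> MI(0) on syn_MI0_s42 - 4000 draws, NOT successful
#>   failed criteria: R-hat, bulk-ESS, tail-ESS, ESS ratio

subset(fit$summary, parameter %in% c("mu_Y_Glc", "mu_LAB_Glc", "k_AAB", "sigma"))
#>     parameter       mean   ci_lower   ci_upper     rhat   ess_bulk   ess_tail
#> 1    mu_Y_Glc 0.07784960 0.02837326 0.15347152 1.861044   5.829548   21.88801
#> 3  mu_LAB_Glc 0.21676370 0.17865434 0.27293178 1.701082   6.363398   29.93421
#> 13      k_AAB 0.28552509 0.26711047 0.30798682 1.275922  11.342149  249.72927
#> 25      sigma 0.02814249 0.02404694 0.03330315 1.020432 221.184833 3011.51907

psis_loo(fit$log_lik)
#> <ferm_loo> elpd = 200.42 (se 8.1) over 96 observations; max Pareto k = 0.15
```

The trial was generated with `mu_LAB_Glc = 0.19` (unit-peak scale) and
noise sd 0.03; the fit recovers both (`mu_LAB_Glc` ≈ 0.22, `sigma` ≈
0.028). The `NOT successful` verdict is the point, not a defect: the
convergence criteria are strict, and at this short 4 × 60k protocol the
well-identified parameters have converged (see `sigma`'s R̂) while the
weakly identified kinetic ridges have not. The parameter-recovery
experiments in `tests/testthat/test-acceptance.R` run 4 × 300k iterations
per fit (~1 min each) and reach ≥ 90% credible-interval coverage of the
generating parameters.

A full campaign over variants × datasets, with caching and per-task
verdicts, runs through `plan_pipeline()` / `run_pipeline()`, and
`assessment_table()` condenses it into the per-variant
`BMA_w / OSR / ESR` table.

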