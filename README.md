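# ipdpool

Two-stage pooled analysis of multisite randomized trials with a binary
outcome, built for collaboratives in which several centers each run a small
trial of the same question — the motivating setting is jail-initiated
medication for opioid use disorder (extended-release naltrexone or interim
methadone), with or without patient navigation, against enhanced treatment
as usual, with a binary diagnosis endpoint six months after release.

The package provides, as tested and exported building blocks:

* a participant-level data model with CONSORT-style post-randomization
  exclusion filters (prison transfer, incarcerated at follow-up, deceased)
  and the conservative **missing-as-positive** imputation rule for
  participants alive and in the community;
* stage 1: per-study covariate-adjusted logistic fits of the treatment
  log-odds ratio (own IRLS with separation monitoring and a Firth
  penalized fallback, so resampling always returns finite statistics);
* stage 2: inverse-variance (common-effect) pooling
  `theta_p = sum(w_j * theta_j) / sum(w_j)`, `w_j = 1 / Var(theta_j)`;
* a **within-study permutation test** of the pooled log-OR (add-one rule,
  one- and two-sided), with an exhaustive-enumeration exact oracle;
* a **stratified bootstrap** percentile confidence interval (resampling
  within study × arm strata, arm sizes fixed);
* a **Bayesian hierarchical logistic model** (partial pooling of study
  effects, half-normal prior on the between-study SD) sampled by an
  adaptive Metropolis-within-Gibbs scheme with split-R-hat and ESS
  diagnostics;
* a synthetic multi-site cohort generator whose defaults encode the
  three-site design registry (arm sizes 58/52, 29/21/19, 46/54/51;
  combined N = 330) and published baseline marginals, plus
  operating-characteristics simulations (type-I error, coverage, power,
  recovery, credible-interval calibration).

The methods vignette (`vignettes/pooled-multisite-analysis.Rmd`) documents
the model, priors, numerical choices and the generator's scope.

## Worked example

```r
library(ipdpool)

cfg    <- sim_config(seed = 42)          # three-site registry defaults
cohort <- simulate_cohort(cfg)           # 330 participants, MCAR missingness
fit    <- ipd_pool(cohort, contrast = "any_med",
                   permutations = 5000, bootstrap = 2000, seed = 1)
print(fit)
```

```
Two-stage pooled analysis, contrast 'any_med' (n = 330, 3 studies)
Inverse-variance pooled treatment effect
  site1    theta =  0.3462 (SE 0.4825)  weight 38.7%
  site2    theta = -0.5826 (SE 0.6728)  weight 19.9%
  site3    theta = -1.3400 (SE 0.4670)  weight 41.3%
  pooled   theta = -0.5360 (SE 0.3003), OR = 0.585
  permutation p (two-sided) = 0.0600  [B = 5000]
  bootstrap 95% CI for OR: [0.311, 1.003]  [B = 2000]
```

Reading this: each line of the study block is one trial's covariate-adjusted
treatment log-odds ratio with its standard error and inverse-variance
weight; `pooled` is their weighted average — here an odds ratio of 0.585,
i.e. assignment to any medication arm is associated with lower odds of a
positive six-month diagnosis *in this simulated cohort*, whose generating
conditional odds ratio is 0.67.  The permutation p-value is the fraction
(add-one corrected) of within-study label reshuffles whose pooled statistic
is at least as extreme, and the bootstrap interval is the percentile
interval of the pooled estimate over stratified resamples.  Crude group
proportions are in `fit$crude` (here 70% of treated vs 80% of control
participants positive after the missing-as-positive rule), and
`summary(fit)`, `coef(fit)`, `confint(fit)` and `plot(fit)` behave as for
any fitted-model object.

The full pipeline — exclusions, imputation, baseline table, both contrasts,
optional Bayesian fit, JSON report — runs from a single config:

```r
report <- run_primary_analysis(list(simulation = list(seed = 42),
                                    permutations = 5000, bootstrap = 2000,
                                    bayes = TRUE, seed = 42))
write_report_json(report, "report.json")
```

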