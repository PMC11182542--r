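---
title: "Pooled analysis of multisite randomized trials with a binary outcome"
author: "ipdpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled analysis of multisite randomized trials with a binary outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipdpool)
```

## The problem

Several research centers each run a randomized trial of the same clinical
question — here, whether medication for opioid use disorder (extended-release
naltrexone or interim methadone) initiated in jail, with or without a patient
navigation add-on, reduces the probability of meeting diagnostic criteria for
opioid use disorder six months after release, relative to enhanced treatment
as usual (overdose education and referrals).  Each trial is small; none is
decisive on its own.  `ipdpool` implements the two-stage
individual-participant-data analysis used for such collaboratives: fit the
treatment effect within each study with covariate adjustment, then pool the
study effects, and attach randomization-based inference that respects the
multi-site structure.

The unit of analysis is the randomized participant, carried as one row of a
plain data frame (`cohort_columns()` documents the schema).  Two features of
the jail setting shape the data model:

* **Post-randomization exclusions.** Participants transferred to prison,
  incarcerated at the time of their six-month interview, or deceased cannot
  contribute a community outcome; `apply_exclusions()` removes them and
  accounts for every removal, CONSORT-style.
* **Worst-case imputation.** A participant who is alive and in the community
  but misses the six-month assessment is counted as *positive* (still meeting
  diagnostic criteria).  `impute_missing_as_positive()` implements this
  deliberately conservative rule; it biases the estimated benefit of
  treatment toward the null whenever treatment actually helps, which is the
  point — the analysis reports the most pessimistic defensible effect.
  Deceased participants are excluded rather than imputed, because the rule
  applies only to those alive and in the community (this choice is
  configurable for sensitivity analyses in the sense that the exclusion
  stage can be bypassed).

## The estimator

For study $j$, with $Y_i$ the binary outcome, $T_i$ the treatment indicator
of the contrast under study and $x_i$ the baseline covariates (age centered
at the study mean; female; race dummy-coded with Black as reference;
unhoused; any prior cocaine/amphetamine use),

$$\operatorname{logit} P(Y_i = 1) = \alpha_j + \theta_j T_i + x_i'\beta_j .$$

$\hat\theta_j$ is the maximum-likelihood treatment coefficient and
$v_j = \widehat{\operatorname{Var}}(\hat\theta_j)$ comes from the inverse
observed information.  Stage two pools by inverse variance:

$$\hat\theta_p = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j},
  \qquad w_j = 1/v_j, \qquad
  \operatorname{SE}(\hat\theta_p) = \Big(\sum_j w_j\Big)^{-1/2}.$$

This is common-effect (fixed-effect) pooling; between-study heterogeneity is
deliberately *not* modeled in the frequentist stage and lives in the Bayesian
sensitivity model instead.  Two contrasts are built in: any medication versus
control (`"any_med"`, collapsing the medication and medication-plus-navigation
arms into one treated group) and navigation versus medication alone (`"pn"`,
using only the studies that randomized both).  Eligibility is derived from
the arms present in the data, never from hard-coded site names; note that in
the motivating collaborative the published methods text and the design table
disagree about *which* two sites carried navigation arms, which is exactly
why eligibility here is data-driven.

### Separation and the Firth fallback

With small arms and resampling, a study fit occasionally separates (a
predictor perfectly classifies the outcome) and the MLE diverges.  The IRLS
path is monitored: any coefficient exceeding 10 in absolute value, a
deviance that stops decreasing after step-halving, or failure to converge in
100 iterations (relative deviance change below $10^{-8}$) triggers a refit
with Firth's Jeffreys-prior penalization, which always returns a finite
estimate; such fits carry a `penalized` flag and resampling replicates that
needed one are counted, never dropped.  On a 2×2 table the Firth estimate
equals the log cross-ratio with ½ added to every cell, which is how the
implementation is unit-tested.

### Randomization inference

`permutation_test()` realizes the randomization null by permuting arm labels
*within each study* (arm counts fixed) and re-running the entire two-stage
estimator per replicate.  P-values use the add-one rule
$(\#\{|\hat\theta_p^{(b)}| \ge |\hat\theta_p|\} + 1)/(B + 1)$, so
$p \in [1/(B+1),\, 1]$.  Both sidednesses are computed: the one-sided value
tests the null $\theta_p \le 0$ against $\theta_p > 0$ — kept in that
orientation because that is how the motivating analysis stated it, even
though the hypothesized benefit corresponds to $\theta_p < 0$ — and the
two-sided value is the headline default, matching how the result was
reported.  `exact_permutation_p()` enumerates all within-study assignments
(capped at 50,000) and is the testing oracle for the Monte-Carlo version.

`bootstrap_ci()` resamples participants with replacement within
study-by-arm strata, keeping every design fixed at its arm sizes, and
reports the percentile interval of the replicate $\hat\theta_p$.  Percentile
(rather than BCa or studentized) intervals are a declared, swappable choice:
they are transformation-equivariant, so the odds-ratio interval is exactly
the exponential of the log-odds-ratio interval.  Defaults are 5,000
permutations and 2,000 bootstrap replicates; the operating-characteristic
simulations use 200 of each.

### The Bayesian sensitivity model

`fit_bayes_hierarchical()` replaces the two-stage point estimate with
partial pooling:

$$Y_{ij} \sim \text{Bernoulli}\big(\operatorname{logit}^{-1}(\alpha_j +
x_{ij}'\beta_j + \theta_j T_{ij})\big), \quad
\theta_j \sim N(\theta_p, \tau^2), \quad
\theta_p \sim N(0, 10^2), \quad \tau \sim \text{Half-N}(1),$$

with $N(0, 10^2)$ priors on all nuisance coefficients.  The source analysis
reported Bayesian study-specific *and* pooled credible intervals but stated
no model, priors or software; this hierarchy is the declared interpretation
consistent with that reporting, and its wide credible intervals (between-study
heterogeneity with only three studies) are expected behavior, not a target.

Sampling is an adaptive random-walk Metropolis-within-Gibbs scheme written
for this model: scalar random-walk updates for study coefficients and
$\theta_j$ (with the linear predictor updated incrementally), a conjugate
Gibbs draw for $\theta_p$, and a log-scale random walk for $\tau$ with the
half-normal prior and Jacobian.  Internally the sampler works in a centered
parametrization (all non-intercept design columns mean-centered), a linear
reparametrization that changes only the intercept's meaning and markedly
decorrelates the updates.  Warmup equals the number of retained iterations
and is discarded; proposal scales adapt only during warmup (targeting
roughly 20–40% acceptance, clipped to $[10^{-3}, 5]$), so retained draws
come from a fixed kernel.  Every parameter gets split-$\widehat R$ and a
Geyer initial-positive-sequence effective sample size; any
$\widehat R > 1.05$ or ESS $< 100$ raises a prominent non-convergence flag
but still returns the result — the caller decides.  `bayes_pool_normal()`
swaps the Bernoulli likelihood for fixed study summaries
$\hat\theta_j \sim N(\theta_j, v_j)$; with $\tau = 0$ and a flat prior its
posterior is the conjugate normal centered at the inverse-variance pool,
the closed-form oracle used to validate the MCMC machinery, and with no
studies it reproduces the prior.

## The synthetic cohort generator

No participant-level data from the motivating trials are deposited, so the
generator is a first-class module, not a test fixture.  Its defaults encode
the published three-site design registry (arm sizes 58/52, 29/21/19,
46/54/51; combined N = 330) and the published baseline marginals: age
truncated-normal with mean 39.2 and SD 10.9 on [18, 80]; 21.2% female;
49.1/40.9/10.0% Black/White/Other; 29.4% Hispanic; 31.9% unhoused.  The
prevalence of any prior cocaine/amphetamine use is not printed in the source
tables (only days-of-use means are); 0.70 was chosen once as consistent
with a mean of ~15 of the past 30 days and is documented here rather than
revisited.  Outcomes follow the logistic model above with default study
intercepts of 0.75 on the log-odds scale (control-arm prevalence near the
printed 75%), a default conditional treatment log-OR of $\log 0.67$ in
every study, and $\log 0.61$ for the navigation increment where a
navigation arm exists.  Default covariate effects are modest values fixed
once (−0.015 per year of age, −0.25 female, +0.15 White, −0.20 other race,
+0.30 unhoused, +0.40 stimulant use); they exist so that adjustment does
something, not to match any published coefficient.

Treatment effects are placed on the *conditional* (covariate-adjusted)
log-odds scale — the same estimand the adjusted logistic model targets.
Because the odds ratio is noncollapsible, the implied crude odds ratio is
closer to 1 than the conditional one; the generator documents rather than
reconciles this.

Follow-up is a second pass: exclusion statuses are assigned independently of
outcome at configured rates (the published flow — 48 prison transfers and
110 incarcerated at follow-up among 488 enrolled — corresponds to rates of
roughly 0.10 and 0.23, but the default is 0 so the generated cohort *is* the
analytic registry), and outcomes among in-community participants are masked
either completely at random (default rate 0.20) or with a logit shift for
latent positives (`outcome_dependent`), which is what makes the worst-case
imputation rule bite.

Determinism: one root integer seed; every study, the follow-up pass, every
chain and every resampling scheme draws from a fixed substream derived by
integer offsets, so results are byte-identical across runs and stable when
studies are added or removed.

What the generator does **not** emulate: visit schedules, medication
adherence trajectories, time-to-event structure, site-level differences in
covariate distributions, or outcome-dependent exclusion.  Passing
calibration tests therefore show that the machinery is correct under the
stated generative model — not that the motivating trials' published
estimates are reproduced, which is impossible without their data.

## Operating characteristics and problem sizes

The `*_sim()` functions measure the estimator on *fully observed* cohorts
(missingness and exclusion rates 0).  This is intentional: missing-as-positive
imputation is a deliberate distortion of the estimand, so estimator
calibration is evaluated against the clean generative effect, and the
imputation rule is tested separately for its defining property (it can only
raise prevalence, and equals the complete-case analysis exactly when nothing
is missing).

Sizes used by the test suite and the acceptance script, chosen as the
package's own trade-off between Monte-Carlo error and turnaround: type-I
error and bootstrap coverage use 300 simulated cohorts at the registry arm
sizes with 200 resampling replicates each; parameter recovery uses 300
replicates at 10× the registry sizes; the permutation oracle instance has
$\binom{12}{6} = 924$ assignments against B = 5,000 Monte-Carlo draws;
Bayesian credible-interval calibration uses 100 hierarchical fits with 2
chains × 1,500 retained iterations.  Power along the grid
$\theta \in \{0, 0.3, 0.6, 0.9\}$ uses common random numbers so the curve
is monotone up to coupling noise.

## Numerical choices, degenerate inputs, limitations

* IRLS: relative deviance tolerance $10^{-8}$, 100 iterations, weights
  floored at $10^{-10}$; Newton steps are halved when the deviance rises.
* Rank-deficient designs (a covariate level absent from a bootstrap
  resample) are handled by QR column pruning before fitting; pruned
  coefficients return `NA` without disturbing the treatment coefficient.
* Single-level covariates in a study are dropped with a warning, not an
  error; missing baseline covariate values are imputed by within-study
  median/mode with a warning, keeping all randomized in-community
  participants in the model.
* Percentile endpoints use R's default empirical quantile; credible
  intervals are equal-tailed percentiles of retained draws; percent
  displays round half to even to one decimal in the baseline table and to
  whole percents for crude proportions.
* Ties in the permutation statistic are counted as "at least as extreme"
  with a $10^{-12}$ tolerance, so the null-centered case returns p = 1.
* The baseline summary reports SD 0.0 with a warning for single-record
  groups.
* Limitations: no random-effects frequentist pooling, no
  treatment-by-covariate interactions, no BCa or studentized bootstrap, no
  model comparison or posterior predictive checks, and the Bayesian model
  is one declared interpretation of an under-specified published analysis.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42)
cohort <- simulate_cohort(cfg)
fit <- ipd_pool(cohort, contrast = "any_med",
                permutations = 5000, bootstrap = 2000, seed = 1)
print(fit)
summary(fit)

report <- run_primary_analysis(list(simulation = list(seed = 42),
                                    permutations = 5000, bootstrap = 2000,
                                    bayes = TRUE, seed = 42))
print(report)
```
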