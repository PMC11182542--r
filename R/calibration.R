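# Operating-characteristics simulations for the two-stage estimator and its
# resampling inference.  These evaluate the estimator on fully observed
# cohorts (no missingness, no exclusions): the missing-as-positive rule is a
# deliberate worst-case distortion of the estimand, so calibration is
# measured against the clean generative effect.

#' Simulation configuration for calibration studies
#'
#' The three-site registry at `n_scale` times its arm sizes, complete
#' follow-up, a common conditional treatment log-OR `theta` in every study
#' and no additional navigation effect, with the default covariate
#' distributions and effects.
#'
#' @param theta Common conditional treatment log-OR.
#' @param n_scale Integer multiplier on every arm size.
#' @param seed Root seed.
#' @return A [sim_config()].
#' @export
calibration_config <- function(theta = 0, n_scale = 1L, seed = 1L) {
  base <- default_designs()
  designs <- lapply(base, function(d) {
    study_design(d$study_id,
                 n_med = d$arm_sizes["MED"] * n_scale,
                 n_etau = d$arm_sizes["ETAU"] * n_scale,
                 n_med_pn = if (d$has_pn_arm) d$arm_sizes["MED_PN"] * n_scale else 0,
                 medication_type = d$medication_type)
  })
  sim_config(
    designs = designs,
    theta_med = rep(theta, length(designs)),
    theta_pn = ifelse(vapply(designs, `[[`, logical(1), "has_pn_arm"), 0, NA),
    missingness = list(mechanism = "MCAR", rate = 0),
    seed = seed
  )
}

#' Type-I error of the pooled permutation test
#'
#' Simulates null three-site cohorts (common treatment log-OR 0), runs the
#' covariate-adjusted permutation test on each, and reports the rejection
#' rate at `alpha` together with all simulated p-values (for
#' super-uniformity checks).
#'
#' @param n_datasets Number of simulated cohorts (default 300).
#' @param B Permutation replicates per cohort (default 200).
#' @param alpha Nominal level (default 0.05, two-sided).
#' @param seed Root seed.
#' @param covariates Adjustment set used in the fits.
#' @return List with `rate`, `p_values`, `n_datasets`, `B`, `alpha`.
#' @export
type1_error_sim <- function(n_datasets = 300L, B = 200L, alpha = 0.05,
                            seed = 1L, covariates = DEFAULT_COVARIATES) {
  p_values <- vapply(seq_len(n_datasets), function(i) {
    cfg <- calibration_config(theta = 0, seed = substream_seed(seed, i))
    records <- simulate_cohort(cfg)
    suppressWarnings(
      permutation_test(records, "any_med", covariates, B = B,
                       seed = substream_seed(seed, 100000L + i))$p_two_sided
    )
  }, numeric(1))
  list(rate = mean(p_values <= alpha), p_values = p_values,
       n_datasets = n_datasets, B = B, alpha = alpha)
}

#' Parameter recovery of the pooled estimator
#'
#' Simulates cohorts with a known common conditional log-OR and reports the
#' replicate mean of the two-stage pooled estimate with its Monte-Carlo
#' standard error.
#'
#' @param theta True common conditional log-OR (default log 0.67).
#' @param n_scale Arm-size multiplier (default 10).
#' @param n_reps Replicates (default 300).
#' @param seed Root seed.
#' @param covariates Adjustment set.
#' @return List with `mean_theta_p`, `mc_se`, `theta_true`, `estimates`.
#' @export
recovery_sim <- function(theta = log(0.67), n_scale = 10L, n_reps = 300L,
                         seed = 1L, covariates = DEFAULT_COVARIATES) {
  est <- vapply(seq_len(n_reps), function(i) {
    cfg <- calibration_config(theta = theta, n_scale = n_scale,
                              seed = substream_seed(seed, i))
    records <- simulate_cohort(cfg)
    encs <- encode_eligible_studies(records, "any_med", covariates)
    pool_from_encodings(encs)$theta_p
  }, numeric(1))
  list(mean_theta_p = mean(est), mc_se = stats::sd(est) / sqrt(n_reps),
       theta_true = theta, estimates = est)
}

#' Coverage of the stratified bootstrap interval
#'
#' Simulates cohorts at the registry arm sizes with a known common
#' conditional log-OR and reports how often the bootstrap percentile
#' interval covers it.
#'
#' @inheritParams recovery_sim
#' @param n_datasets Simulated cohorts (default 300).
#' @param B Bootstrap replicates per cohort (default 200).
#' @param level Interval level (default 0.95).
#' @return List with `coverage`, `n_datasets`, `B`, `level`, `theta_true`.
#' @export
coverage_sim <- function(theta = log(0.67), n_datasets = 300L, B = 200L,
                         level = 0.95, seed = 1L,
                         covariates = DEFAULT_COVARIATES) {
  covered <- vapply(seq_len(n_datasets), function(i) {
    cfg <- calibration_config(theta = theta, seed = substream_seed(seed, i))
    records <- simulate_cohort(cfg)
    ci <- suppressWarnings(
      bootstrap_ci(records, "any_med", covariates, B = B, level = level,
                   seed = substream_seed(seed, 200000L + i))
    )
    ci$lower <= theta && theta <= ci$upper
  }, logical(1))
  list(coverage = mean(covered), n_datasets = n_datasets, B = B,
       level = level, theta_true = theta)
}

#' Power of the permutation test along an effect grid
#'
#' Rejection rate of the two-sided permutation test at each true log-OR in
#' `theta_grid`, using common random numbers across grid points (the same
#' dataset and permutation seeds are reused for every theta), so the power
#' curve is monotone up to coupling noise.
#'
#' @param theta_grid Vector of true common log-ORs.
#' @param n_datasets Simulated cohorts per grid point.
#' @param B Permutation replicates per cohort.
#' @param alpha Nominal level (two-sided).
#' @param seed Root seed.
#' @param covariates Adjustment set.
#' @return Data frame with `theta` and `power`.
#' @export
power_sim <- function(theta_grid = c(0, 0.3, 0.6, 0.9), n_datasets = 60L,
                      B = 100L, alpha = 0.05, seed = 1L,
                      covariates = DEFAULT_COVARIATES) {
  power <- vapply(theta_grid, function(theta) {
    rejections <- vapply(seq_len(n_datasets), function(i) {
      cfg <- calibration_config(theta = theta, seed = substream_seed(seed, i))
      records <- simulate_cohort(cfg)
      p <- suppressWarnings(
        permutation_test(records, "any_med", covariates, B = B,
                         seed = substream_seed(seed, 300000L + i))$p_two_sided
      )
      p <= alpha
    }, logical(1))
    mean(rejections)
  }, numeric(1))
  data.frame(theta = theta_grid, power = power)
}

#' Credible-interval calibration of the hierarchical model
#'
#' Repeatedly simulates registry-size cohorts with a common true log-OR,
#' fits the Bayesian hierarchical model, and reports how often the 95%
#' credible interval for the pooled effect covers the truth.
#'
#' @inheritParams recovery_sim
#' @param n_fits Number of replicate fits (default 100).
#' @param chains,iter Passed to [fit_bayes_hierarchical()].
#' @return List with `coverage`, `n_fits`, `theta_true`,
#'   `n_nonconverged`.
#' @export
bayes_calibration_sim <- function(theta = log(0.67), n_fits = 100L,
                                  chains = 2L, iter = 1500L, seed = 1L,
                                  covariates = DEFAULT_COVARIATES) {
  nonconv <- 0L
  covered <- vapply(seq_len(n_fits), function(i) {
    cfg <- calibration_config(theta = theta, seed = substream_seed(seed, i))
    records <- simulate_cohort(cfg)
    fit <- suppressWarnings(
      fit_bayes_hierarchical(records, "any_med", covariates,
                             chains = chains, iter = iter,
                             seed = substream_seed(seed, 400000L + i))
    )
    if (fit$non_convergence) nonconv <<- nonconv + 1L
    ci <- fit$intervals[fit$intervals$parameter == "theta_p", ]
    ci$lower <= theta && theta <= ci$upper
  }, logical(1))
  list(coverage = mean(covered), n_fits = n_fits, theta_true = theta,
       n_nonconverged = nonconv)
}
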