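#' Two-stage pooled analysis of a multisite trial
#'
#' The package's central fitting function.  Stage 1 fits a covariate-adjusted
#' logistic model in every eligible study and extracts the treatment log-odds
#' ratio; stage 2 combines the study effects by inverse-variance
#' (common-effect) weighting.  Optionally adds a within-study permutation
#' test of the pooled effect and a stratified bootstrap percentile
#' confidence interval, each re-running the full two-stage estimator per
#' replicate.
#'
#' If the records still carry follow-up statuses other than `in_community`
#' or missing outcomes, the standard preparation is applied first: exclusion
#' of prison transfers, participants incarcerated at follow-up and the
#' deceased, then worst-case imputation of missing outcomes as positive
#' (`prepare = TRUE`, the default).
#'
#' @param records Participant records (see [cohort_columns()]).
#' @param contrast `"any_med"` (any medication vs control, the default) or
#'   `"pn"` (medication plus navigation vs medication alone).
#' @param covariates Adjustment set; default age, sex, race, housing status
#'   and prior stimulant use.  `NULL` for crude fits.
#' @param permutations Permutation replicates for the test (0 = skip).
#' @param bootstrap Bootstrap replicates for the interval (0 = skip).
#' @param level Confidence level for the bootstrap interval.
#' @param seed Integer seed driving both resampling schemes.
#' @param prepare Apply exclusions and missing-as-positive imputation first.
#' @return Object of class `ipd_pool` with components `pooled`
#'   (a `pooled_estimate`), `studies` (per-study data frame), `permutation`,
#'   `bootstrap` (or `NULL`), `exclusions`, `crude` (group outcome
#'   proportions), `contrast`, `covariates`, `n`, `seed`, `call`.
#'
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 42))
#' fit <- ipd_pool(cohort, permutations = 200, bootstrap = 200, seed = 1)
#' print(fit)
#' coef(fit)
#' confint(fit)
#' @export
ipd_pool <- function(records, contrast = c("any_med", "pn"),
                     covariates = DEFAULT_COVARIATES, permutations = 0L,
                     bootstrap = 0L, level = 0.95, seed = NULL,
                     prepare = TRUE) {
  if (is.character(contrast)) contrast <- match.arg(contrast)
  contrast <- as_contrast(contrast)
  cl <- match.call()
  exclusions <- NULL
  if (prepare) {
    if (any(is.na(records$follow_up_status))) {
      stop_field("follow_up_status",
                 "unset; run apply_followup_process() or set statuses")
    }
    excl <- apply_exclusions(records)
    records <- impute_missing_as_positive(excl$records)
    exclusions <- excl$report
  } else {
    validate_records(records, require_status = TRUE)
    if (any(records$outcome == "missing")) {
      stop_field("outcome", "missing outcomes present; impute or set prepare = TRUE")
    }
  }
  encs <- encode_eligible_studies(records, contrast, covariates)
  pooled <- pool_from_encodings(encs)
  perm <- NULL
  boot <- NULL
  if (permutations > 0) {
    perm <- permutation_test(records, contrast, covariates,
                             B = permutations,
                             seed = if (is.null(seed)) NULL
                                    else substream_seed(seed, 1L))
  }
  if (bootstrap > 0) {
    boot <- bootstrap_ci(records, contrast, covariates, B = bootstrap,
                         level = level,
                         seed = if (is.null(seed)) NULL
                                else substream_seed(seed, 2L))
  }
  structure(
    list(pooled = pooled, studies = pooled$studies, permutation = perm,
         bootstrap = boot, exclusions = exclusions,
         crude = report_crude_proportions(records, contrast),
         contrast = contrast, covariates = covariates,
         n = sum(pooled$studies$n_treated + pooled$studies$n_reference),
         seed = seed, call = cl),
    class = "ipd_pool"
  )
}

#' @export
print.ipd_pool <- function(x, ...) {
  cat(sprintf("Two-stage pooled analysis, contrast '%s' (n = %d, %d studies)\n",
              x$contrast$name, x$n, nrow(x$studies)))
  print(x$pooled)
  if (!is.null(x$permutation)) {
    cat(sprintf("  permutation p (two-sided) = %.4f  [B = %d]\n",
                x$permutation$p_two_sided, x$permutation$B))
  }
  if (!is.null(x$bootstrap)) {
    cat(sprintf("  bootstrap %g%% CI for OR: [%.3f, %.3f]  [B = %d]\n",
                100 * x$bootstrap$level, x$bootstrap$or_lower,
                x$bootstrap$or_upper, x$bootstrap$B))
  }
  invisible(x)
}

#' @export
coef.ipd_pool <- function(object, ...) {
  c(theta_p = object$pooled$theta_p)
}

#' @export
vcov.ipd_pool <- function(object, ...) {
  matrix(object$pooled$se_p^2, 1, 1,
         dimnames = list("theta_p", "theta_p"))
}

#' @export
confint.ipd_pool <- function(object, parm = "theta_p", level = 0.95, ...) {
  if (!is.null(object$bootstrap) && level == object$bootstrap$level) {
    ci <- c(object$bootstrap$lower, object$bootstrap$upper)
  } else {
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- object$pooled$theta_p + c(-1, 1) * z * object$pooled$se_p
  }
  out <- matrix(ci, 1, 2, dimnames = list(
    "theta_p", sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))))
  out
}

#' @export
summary.ipd_pool <- function(object, ...) {
  structure(list(fit = object), class = "summary.ipd_pool")
}

#' @export
print.summary.ipd_pool <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nCrude outcome proportions:\n")
  print(f$crude, row.names = FALSE)
  if (!is.null(f$exclusions)) print(f$exclusions)
  invisible(x)
}

#' Forest-style plot of the study and pooled estimates
#'
#' @param x An `ipd_pool` fit.
#' @param ... Passed to [graphics::plot.default()].
#' @export
plot.ipd_pool <- function(x, ...) {
  df <- x$studies
  k <- nrow(df)
  est <- c(df$theta_hat, x$pooled$theta_p)
  se <- c(df$se, x$pooled$se_p)
  labels <- c(df$study_id, "pooled")
  ypos <- rev(seq_len(k + 1))
  graphics::plot(est, ypos, xlim = range(est - 2 * se, est + 2 * se),
                 ylim = c(0.5, k + 1.5), yaxt = "n", pch = c(rep(15, k), 18),
                 xlab = "treatment log-odds ratio", ylab = "", ...)
  graphics::segments(est - 1.96 * se, ypos, est + 1.96 * se, ypos)
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = ypos, labels = labels, las = 1)
  invisible(x)
}

#' Crude outcome proportions per contrast group
#'
#' Positive-outcome proportion in the treated and reference groups of a
#' contrast, with counts, exact proportions, and whole-percent display
#' values.
#'
#' @param records Post-imputation analytic records.
#' @param contrast A [contrast_spec()] or its name.
#' @return Data frame with columns `group`, `n`, `positive`, `proportion`
#'   (full precision), `percent` (rounded to whole percents; `NA` for an
#'   empty group).
#' @examples
#' # 91 positives among 122 -> 74.6% unrounded, displayed as 75%
#' @export
report_crude_proportions <- function(records, contrast) {
  contrast <- as_contrast(contrast)
  groups <- list(treated = contrast$treated_arms,
                 reference = contrast$reference_arms)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    d <- records[records$arm %in% groups[[g]], , drop = FALSE]
    n <- nrow(d)
    pos <- sum(d$outcome == "positive")
    data.frame(group = g, n = n, positive = pos,
               proportion = if (n > 0) pos / n else NA_real_,
               percent = if (n > 0) round(100 * pos / n) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out
}
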