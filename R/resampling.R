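# Resampling inference for the pooled effect: a within-study permutation
# test (randomization null) and a stratified bootstrap percentile interval,
# each re-running the full two-stage estimator per replicate.

# Encode every eligible study once; resampling replicates then only permute
# the treatment column or resample rows, never re-encode.
encode_eligible_studies <- function(records, contrast, covariates) {
  contrast <- as_contrast(contrast)
  ids <- eligible_studies(records, contrast)
  if (length(ids) == 0L) {
    stop(sprintf("no study is eligible for contrast '%s'", contrast$name),
         call. = FALSE)
  }
  lapply(ids, function(s) {
    encode_covariates(records[records$study_id == s, , drop = FALSE],
                      covariates, contrast)
  })
}

pool_from_encodings <- function(encs) {
  fits <- lapply(encs, fit_encoded_study)
  pooled <- pool_estimates(fits)
  pooled$n_penalized <- sum(vapply(fits, `[[`, logical(1), "penalized"))
  pooled
}

#' Permute treatment labels within study
#'
#' Reassigns arm labels uniformly at random within each study, preserving
#' every study's arm counts; covariates and outcomes stay attached to their
#' participants.  This realizes the randomization null used by
#' [permutation_test()].
#'
#' @param records Participant records.
#' @param seed Optional integer seed.
#' @return Records with permuted `arm` (and consistent `medication_type`).
#' @export
permute_within_study <- function(records, seed = NULL) {
  validate_records(records, require_status = FALSE)
  if (!is.null(seed)) set.seed(seed)
  for (s in unique(records$study_id)) {
    idx <- which(records$study_id == s)
    med <- setdiff(unique(records$medication_type[idx]), "none")
    new_arm <- records$arm[idx][sample.int(length(idx))]
    records$arm[idx] <- new_arm
    records$medication_type[idx] <-
      ifelse(new_arm == "ETAU", "none", med[1] %||% "none")
  }
  records
}

#' Permutation test of the pooled treatment log-odds ratio
#'
#' Builds the randomization null distribution of the pooled log-OR by
#' permuting treatment labels within each study (arm counts preserved) and
#' re-running the full two-stage estimator — per-study adjusted logistic fits
#' and inverse-variance pooling — on every permuted dataset.  P-values use
#' the add-one rule \eqn{(\#\{\cdot\} + 1)/(B + 1)}, which includes the
#' observed dataset as one realization of the null; the two-sided value
#' counts null draws at least as extreme in absolute value, the one-sided
#' value (alternative: pooled log-OR > 0) counts null draws at least as
#' large.  Replicates whose study fits need Firth penalization are retained
#' and counted, never dropped.
#'
#' @param records Analytic records (exclusion-filtered and imputed).
#' @param contrast A [contrast_spec()] or its name.
#' @param covariates Adjustment set; `NULL` for crude fits.
#' @param B Number of permutation replicates (default 5000).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `permutation_result`: `observed_theta_p`,
#'   `null_draws`, `p_two_sided`, `p_one_sided`, `B`, `seed`,
#'   `n_degenerate`.
#' @export
permutation_test <- function(records, contrast,
                             covariates = DEFAULT_COVARIATES, B = 5000L,
                             seed = NULL) {
  if (B < 1) stop_field("B", "must be at least 1")
  encs <- encode_eligible_studies(records, contrast, covariates)
  observed <- pool_from_encodings(encs)
  if (!is.null(seed)) set.seed(seed)
  null_draws <- numeric(B)
  n_degenerate <- 0L
  treat_cols <- vapply(encs, function(e) match("treat", colnames(e$X)),
                       integer(1))
  for (b in seq_len(B)) {
    fits <- vector("list", length(encs))
    for (j in seq_along(encs)) {
      e <- encs[[j]]
      e$treat <- e$treat[sample.int(length(e$treat))]
      e$X[, treat_cols[j]] <- e$treat
      fits[[j]] <- fit_encoded_study(e)
    }
    if (any(vapply(fits, `[[`, logical(1), "penalized"))) {
      n_degenerate <- n_degenerate + 1L
    }
    null_draws[b] <- pool_estimates(fits)$theta_p
  }
  obs <- observed$theta_p
  tol <- 1e-12
  structure(
    list(observed_theta_p = obs, null_draws = null_draws,
         p_two_sided = (sum(abs(null_draws) >= abs(obs) - tol) + 1) / (B + 1),
         p_one_sided = (sum(null_draws >= obs - tol) + 1) / (B + 1),
         B = as.integer(B), seed = seed, n_degenerate = n_degenerate,
         pooled = observed),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test (B = %d): observed pooled theta = %.4f (OR %.3f)\n",
    x$B, x$observed_theta_p, exp(x$observed_theta_p)))
  cat(sprintf("  two-sided p = %.4f, one-sided p (theta_p > 0) = %.4f\n",
              x$p_two_sided, x$p_one_sided))
  if (x$n_degenerate > 0) {
    cat(sprintf("  %d replicate(s) required Firth penalization\n",
                x$n_degenerate))
  }
  invisible(x)
}

#' Exact permutation p-value by exhaustive enumeration
#'
#' Enumerates every within-study assignment of treated labels (all
#' \eqn{\prod_j \binom{n_j}{t_j}} combinations), computes the crude
#' (treatment-only) pooled log-OR for each, and returns the exact two-sided
#' p-value: the fraction of assignments whose absolute pooled statistic is at
#' least the observed one.  Serves as the small-instance oracle for
#' [permutation_test()] run with `covariates = NULL`.
#'
#' @param records Analytic records.
#' @param contrast A [contrast_spec()] or its name.
#' @param max_count Enumeration cap (default 50000 assignments).
#' @return The exact two-sided p-value, with attributes `n_assignments` and
#'   `observed_theta_p`.
#' @export
exact_permutation_p <- function(records, contrast, max_count = 50000) {
  encs <- encode_eligible_studies(records, contrast, covariates = NULL)
  counts <- vapply(encs, function(e) {
    choose(length(e$treat), sum(e$treat == 1))
  }, numeric(1))
  M <- prod(counts)
  if (M > max_count) {
    stop(sprintf("instance too large: %.0f assignments exceed the cap of %d",
                 M, max_count), call. = FALSE)
  }
  # Per study, (theta, weight) across all assignments of the treated set.
  per_study <- lapply(encs, function(e) {
    n <- length(e$treat)
    t_n <- sum(e$treat == 1)
    sets <- utils::combn(n, t_n)
    k <- match("treat", colnames(e$X))
    theta <- numeric(ncol(sets))
    wt <- numeric(ncol(sets))
    for (i in seq_len(ncol(sets))) {
      tr <- numeric(n)
      tr[sets[, i]] <- 1
      e$X[, k] <- tr
      fit <- fit_logit(e$X, e$y)
      theta[i] <- fit$coef[k]
      wt[i] <- 1 / fit$vcov[k, k]
    }
    list(theta = theta, w = wt)
  })
  grid <- do.call(expand.grid, lapply(per_study, function(s) seq_along(s$theta)))
  num <- 0
  den <- 0
  for (j in seq_along(per_study)) {
    num <- num + per_study[[j]]$w[grid[[j]]] * per_study[[j]]$theta[grid[[j]]]
    den <- den + per_study[[j]]$w[grid[[j]]]
  }
  theta_all <- num / den
  obs <- pool_from_encodings(encs)$theta_p
  p <- mean(abs(theta_all) >= abs(obs) - 1e-9)
  structure(p, n_assignments = nrow(grid), observed_theta_p = obs)
}

#' Stratified bootstrap confidence interval for the pooled log-odds ratio
#'
#' Resamples participants with replacement within study-by-arm strata
#' (keeping every arm size fixed at its design value), re-runs the full
#' two-stage estimator on each replicate, and reports the percentile interval
#' of the replicate pooled log-ORs.  The odds-ratio-scale interval is the
#' elementwise exponential of the log-OR interval, so the two are exactly
#' equivariant.  Replicates needing Firth penalization are retained.
#'
#' @inheritParams permutation_test
#' @param B Number of bootstrap replicates (default 2000).
#' @param level Confidence level in (0, 1) (default 0.95).
#' @return Object of class `bootstrap_result`: `level`, `lower`, `upper`
#'   (log-OR scale), `or_lower`, `or_upper`, `observed_theta_p`,
#'   `replicate_draws`, `B`, `seed`, `n_degenerate`.
#' @export
bootstrap_ci <- function(records, contrast, covariates = DEFAULT_COVARIATES,
                         B = 2000L, level = 0.95, seed = NULL) {
  if (B < 1) stop_field("B", "must be at least 1")
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop_field("level", "must be in (0, 1)")
  }
  encs <- encode_eligible_studies(records, contrast, covariates)
  observed <- pool_from_encodings(encs)
  strata <- lapply(encs, function(e) split(seq_along(e$y), e$arm))
  for (j in seq_along(strata)) {
    sizes <- lengths(strata[[j]])
    if (any(sizes == 0L)) {
      stop(sprintf("empty stratum '%s' in study '%s'",
                   names(sizes)[sizes == 0][1], encs[[j]]$study_id),
           call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- numeric(B)
  n_degenerate <- 0L
  for (b in seq_len(B)) {
    fits <- vector("list", length(encs))
    for (j in seq_along(encs)) {
      e <- encs[[j]]
      idx <- unlist(lapply(strata[[j]], function(s) {
        s[sample.int(length(s), length(s), replace = TRUE)]
      }), use.names = FALSE)
      e$X <- e$X[idx, , drop = FALSE]
      e$y <- e$y[idx]
      e$treat <- e$treat[idx]
      fits[[j]] <- fit_encoded_study(e)
    }
    if (any(vapply(fits, `[[`, logical(1), "penalized"))) {
      n_degenerate <- n_degenerate + 1L
    }
    draws[b] <- pool_estimates(fits)$theta_p
  }
  alpha <- (1 - level) / 2
  ci <- stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE)
  structure(
    list(level = level, lower = ci[1], upper = ci[2],
         or_lower = exp(ci[1]), or_upper = exp(ci[2]),
         observed_theta_p = observed$theta_p, replicate_draws = draws,
         B = as.integer(B), seed = seed, n_degenerate = n_degenerate,
         pooled = observed),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "Stratified bootstrap (B = %d): pooled theta = %.4f, %g%% CI [%.4f, %.4f]\n",
    x$B, x$observed_theta_p, 100 * x$level, x$lower, x$upper))
  cat(sprintf("  OR scale: %.3f [%.3f, %.3f]\n", exp(x$observed_theta_p),
              x$or_lower, x$or_upper))
  invisible(x)
}
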