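#' Treatment contrast specifications
#'
#' Two contrasts are defined for the multisite design: `"any_med"` compares
#' any medication arm (medication alone or with patient navigation, collapsed
#' into one treated group) against the control arm, and `"pn"` compares
#' medication plus navigation against medication alone.  A study is eligible
#' for a contrast when it contains at least one treated and one reference
#' arm.
#'
#' @param name `"any_med"` (alias `"ANY_MED_VS_ETAU"`) or `"pn"` (alias
#'   `"MED_PN_VS_MED"`).
#' @return Object of class `contrast_spec` with fields `name`,
#'   `treated_arms`, `reference_arms`.
#' @export
contrast_spec <- function(name = c("any_med", "pn", "ANY_MED_VS_ETAU",
                                   "MED_PN_VS_MED")) {
  name <- match.arg(name)
  name <- switch(name, ANY_MED_VS_ETAU = "any_med", MED_PN_VS_MED = "pn",
                 name)
  spec <- switch(name,
    any_med = list(name = "any_med", treated_arms = c("MED", "MED_PN"),
                   reference_arms = "ETAU"),
    pn = list(name = "pn", treated_arms = "MED_PN", reference_arms = "MED")
  )
  structure(spec, class = "contrast_spec")
}

as_contrast <- function(contrast) {
  if (inherits(contrast, "contrast_spec")) return(contrast)
  contrast_spec(contrast)
}

#' Studies eligible for a contrast
#'
#' @param records Participant records.
#' @param contrast A [contrast_spec()] or its name.
#' @return Character vector of `study_id`s containing at least one treated
#'   and one reference arm, in order of first appearance.
#' @export
eligible_studies <- function(records, contrast) {
  contrast <- as_contrast(contrast)
  ids <- unique(records$study_id)
  keep <- vapply(ids, function(s) {
    arms <- unique(records$arm[records$study_id == s])
    any(arms %in% contrast$treated_arms) && any(arms %in% contrast$reference_arms)
  }, logical(1))
  ids[keep]
}

DEFAULT_COVARIATES <- c("age", "sex", "race", "unhoused", "stimulant_use")

# Canonical design-matrix column order for the full covariate set.
encode_column_order <- function() {
  c("intercept", "treat", "age_c", "female", "race_White", "race_Other",
    "unhoused", "stimulant")
}

#' Encode a single study's records as a logistic design matrix
#'
#' Builds the adjusted model's design: an intercept, the treatment indicator
#' from the contrast (treated arms coded 1, reference arms 0), age centered
#' at the study mean, a female indicator, race dummy-coded with Black as the
#' reference level, and unhoused / stimulant-use indicators.  A covariate
#' with a single observed level in the study carries no information and is
#' dropped with a warning.  Missing baseline covariate values are imputed by
#' the within-study median (continuous) or mode (categorical) with a warning,
#' so all randomized in-community participants stay in the model.
#'
#' @param records Records from one study, restricted to the contrast's arms.
#' @param covariates Subset of `c("age", "sex", "race", "unhoused",
#'   "stimulant_use")`; `NULL` for a crude (treatment-only) model.
#' @param contrast A [contrast_spec()] or its name.
#' @return A list with `X` (design matrix, columns in the order intercept,
#'   treat, age_c, female, race_White, race_Other, unhoused, stimulant as
#'   present), `y` (0/1 outcome, positive = 1), `treat` (the 0/1 treatment
#'   vector) and `dropped` (names of dropped single-level covariates).
#' @export
encode_covariates <- function(records, covariates = DEFAULT_COVARIATES,
                              contrast = "any_med") {
  contrast <- as_contrast(contrast)
  allowed <- c("age", "sex", "race", "unhoused", "stimulant_use")
  if (!is.null(covariates) && !all(covariates %in% allowed)) {
    stop_field("covariates", paste("must be among:",
                                   paste(allowed, collapse = ", ")))
  }
  keep <- records$arm %in% c(contrast$treated_arms, contrast$reference_arms)
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) stop_field("records", "no records in contrast arms")
  treat <- as.numeric(records$arm %in% contrast$treated_arms)
  y <- as.numeric(records$outcome == "positive")

  records <- impute_baseline_covariates(records, covariates)

  cols <- list(intercept = rep(1, nrow(records)), treat = treat)
  if ("age" %in% covariates) {
    cols$age_c <- records$age - mean(records$age)
  }
  if ("sex" %in% covariates) {
    cols$female <- as.numeric(records$sex == "female")
  }
  if ("race" %in% covariates) {
    cols$race_White <- as.numeric(records$race == "White")
    cols$race_Other <- as.numeric(records$race == "Other")
  }
  if ("unhoused" %in% covariates) {
    cols$unhoused <- as.numeric(records$unhoused)
  }
  if ("stimulant_use" %in% covariates) {
    cols$stimulant <- as.numeric(records$stimulant_use)
  }
  dropped <- character(0)
  for (nm in setdiff(names(cols), c("intercept", "treat"))) {
    if (length(unique(cols[[nm]])) < 2L) {
      dropped <- c(dropped, nm)
      cols[[nm]] <- NULL
    }
  }
  if (length(dropped)) {
    warning(sprintf("study '%s': dropping single-level covariate(s): %s",
                    records$study_id[1], paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  order_now <- intersect(encode_column_order(), names(cols))
  X <- do.call(cbind, cols[order_now])
  colnames(X) <- order_now
  list(X = X, y = y, treat = treat, dropped = dropped,
       study_id = records$study_id[1], arm = records$arm)
}

impute_baseline_covariates <- function(records, covariates) {
  if (is.null(covariates)) return(records)
  mode_of <- function(x) names(which.max(table(x)))
  if ("age" %in% covariates && anyNA(records$age)) {
    warning(sprintf("study '%s': imputing %d missing age value(s) by the study median",
                    records$study_id[1], sum(is.na(records$age))), call. = FALSE)
    records$age[is.na(records$age)] <- stats::median(records$age, na.rm = TRUE)
  }
  for (col in intersect(c("sex", "race"), covariates)) {
    if (anyNA(records[[col]])) {
      warning(sprintf("study '%s': imputing missing %s by the study mode",
                      records$study_id[1], col), call. = FALSE)
      records[[col]][is.na(records[[col]])] <- mode_of(records[[col]])
    }
  }
  for (col in intersect(c("unhoused", "stimulant_use"), covariates)) {
    if (anyNA(records[[col]])) {
      warning(sprintf("study '%s': imputing missing %s by the study mode",
                      records$study_id[1], col), call. = FALSE)
      records[[col]][is.na(records[[col]])] <-
        mode_of(records[[col]]) == "TRUE"
    }
  }
  records
}

#' Study-specific covariate-adjusted treatment effect
#'
#' Fits the logistic model for one study by maximum likelihood (IRLS) and
#' returns the treatment coefficient — the study-specific conditional
#' log-odds ratio — with its variance from the inverse observed information.
#' If the MLE path shows separation (any coefficient beyond 10 in absolute
#' value, a non-decreasing deviance, or non-convergence) the study is refit
#' with Firth's Jeffreys-prior penalization, which always yields a finite
#' estimate; the `penalized` flag records this.
#'
#' @param records Analytic records (exclusion-filtered and imputed).
#' @param contrast A [contrast_spec()] or its name.
#' @param covariates Adjustment set (see [encode_covariates()]); `NULL` for a
#'   crude model.
#' @return Object of class `study_estimate`: a list with `study_id`,
#'   `theta_hat`, `variance`, `se`, `n_treated`, `n_reference`, `converged`,
#'   `penalized`, `dropped`.
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 11,
#'   missingness = list(mechanism = "MCAR", rate = 0)))
#' fit_study_logistic(cohort[cohort$study_id == "site1", ], "any_med")
#' @export
fit_study_logistic <- function(records, contrast,
                               covariates = DEFAULT_COVARIATES) {
  contrast <- as_contrast(contrast)
  arms <- unique(records$arm)
  if (!any(arms %in% contrast$treated_arms) ||
      !any(arms %in% contrast$reference_arms)) {
    stop(sprintf("study '%s' lacks a %s arm for contrast '%s'",
                 records$study_id[1],
                 if (any(arms %in% contrast$treated_arms)) "reference" else "treated",
                 contrast$name), call. = FALSE)
  }
  enc <- encode_covariates(records, covariates, contrast)
  if (length(unique(enc$y)) < 2L) {
    stop(sprintf("study '%s': outcome has a single level; treatment effect not estimable",
                 enc$study_id), call. = FALSE)
  }
  fit_encoded_study(enc)
}

# Fit from a pre-built encoding; the fast path used by resampling loops.
fit_encoded_study <- function(enc) {
  fit <- fit_logit(enc$X, enc$y)
  k <- match("treat", colnames(enc$X))
  theta <- fit$coef[k]
  variance <- fit$vcov[k, k]
  structure(
    list(study_id = enc$study_id, theta_hat = theta, variance = variance,
         se = sqrt(variance), n_treated = sum(enc$treat == 1),
         n_reference = sum(enc$treat == 0), converged = fit$converged,
         penalized = fit$penalized, dropped = enc$dropped),
    class = "study_estimate"
  )
}

#' @export
print.study_estimate <- function(x, ...) {
  cat(sprintf(
    "Study %s: theta = %.4f (SE %.4f), OR = %.3f, n = %d vs %d%s\n",
    x$study_id, x$theta_hat, x$se, exp(x$theta_hat), x$n_treated,
    x$n_reference, if (x$penalized) " [Firth]" else ""))
  invisible(x)
}

study_estimates_frame <- function(estimates) {
  if (inherits(estimates, "study_estimate")) estimates <- list(estimates)
  if (is.data.frame(estimates)) {
    need <- c("study_id", "theta_hat", "variance")
    if (!all(need %in% names(estimates))) {
      stop_field("estimates", paste("data frame needs columns:",
                                    paste(need, collapse = ", ")))
    }
    df <- estimates
    if (is.null(df$se)) df$se <- sqrt(df$variance)
    return(df)
  }
  if (!is.list(estimates) || length(estimates) == 0L) {
    stop_field("estimates", "need at least one study estimate")
  }
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(study_id = e$study_id, theta_hat = e$theta_hat,
               variance = e$variance, se = e$se,
               n_treated = e$n_treated %||% NA_integer_,
               n_reference = e$n_reference %||% NA_integer_,
               converged = e$converged %||% TRUE,
               penalized = e$penalized %||% FALSE,
               stringsAsFactors = FALSE)
  }))
}

#' Inverse-variance fixed-effect pooling of study log-odds ratios
#'
#' Combines study-specific treatment log-ORs into the pooled estimate
#' \deqn{\hat\theta_p = \sum_j w_j \hat\theta_j / \sum_j w_j,\qquad
#'       w_j = 1/\widehat{Var}(\hat\theta_j),}
#' with standard error \eqn{(\sum_j w_j)^{-1/2}} — the common-effect
#' (fixed-effect) two-stage estimator.  Works identically for any number of
#' studies; with one study it reduces to that study's estimate.
#'
#' @param estimates A list of `study_estimate` objects, a single one, or a
#'   data frame with columns `study_id`, `theta_hat`, `variance`.
#' @return Object of class `pooled_estimate`: `theta_p`, `se_p`, `weights`
#'   (named by study), `odds_ratio`, and the per-study `studies` data frame.
#' @examples
#' pool_estimates(data.frame(study_id = c("a", "b"),
#'                           theta_hat = c(0.5, -0.3),
#'                           variance = c(0.04, 0.01)))
#' @export
pool_estimates <- function(estimates) {
  df <- study_estimates_frame(estimates)
  if (any(!is.finite(df$variance)) || any(df$variance <= 0)) {
    bad <- df$study_id[which(!is.finite(df$variance) | df$variance <= 0)[1]]
    stop(sprintf("nonpositive variance for study '%s'", bad), call. = FALSE)
  }
  w <- 1 / df$variance
  names(w) <- df$study_id
  theta_p <- sum(w * df$theta_hat) / sum(w)
  structure(
    list(theta_p = theta_p, se_p = sqrt(1 / sum(w)), weights = w,
         odds_ratio = exp(theta_p), studies = df),
    class = "pooled_estimate"
  )
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat("Inverse-variance pooled treatment effect\n")
  df <- x$studies
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-8s theta = %7.4f (SE %.4f)  weight %.1f%%%s\n",
                df$study_id[i], df$theta_hat[i], df$se[i],
                100 * x$weights[i] / sum(x$weights),
                if (isTRUE(df$penalized[i])) " [Firth]" else ""))
  }
  cat(sprintf("  pooled   theta = %7.4f (SE %.4f), OR = %.3f\n",
              x$theta_p, x$se_p, x$odds_ratio))
  invisible(x)
}
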