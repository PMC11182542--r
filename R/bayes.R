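# Bayesian hierarchical sensitivity analysis.  Model:
#   y_ij ~ Bernoulli(logit^-1(alpha_j + x'beta_j + theta_j * treat_ij))
#   theta_j ~ Normal(theta_p, tau^2)
#   theta_p ~ Normal(0, sd_pooled_effect^2)
#   tau     ~ Half-Normal(scale_tau)
#   alpha_j, beta_j ~ Normal(0, sd_nuisance^2)
# Sampled by adaptive random-walk Metropolis within Gibbs: scalar RW updates
# for the study-level coefficients and theta_j (with cached linear
# predictors updated incrementally), a conjugate Gibbs draw for theta_p, and
# a log-scale RW update for tau.  Adaptation runs during warmup only,
# targeting roughly 20-40% acceptance.

#' Prior specification for the hierarchical model
#'
#' @param sd_pooled_effect Prior SD of the pooled log-OR (default 10, weakly
#'   informative on the log-odds scale).
#' @param sd_nuisance Prior SD of study intercepts and covariate
#'   coefficients (default 10).
#' @param scale_tau Half-normal scale of the between-study SD tau
#'   (default 1).
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(sd_pooled_effect = 10, sd_nuisance = 10,
                       scale_tau = 1) {
  # Inf is allowed for the normal prior SDs (a flat prior); the half-normal
  # scale for tau must be finite.
  for (nm in c("sd_pooled_effect", "sd_nuisance", "scale_tau")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 ||
        (nm == "scale_tau" && !is.finite(v))) {
      stop_field(nm, "must be a positive scale")
    }
  }
  structure(list(sd_pooled_effect = sd_pooled_effect,
                 sd_nuisance = sd_nuisance, scale_tau = scale_tau),
            class = "prior_spec")
}

#' Fit the Bayesian hierarchical logistic model
#'
#' Partial-pooling alternative to the frequentist two-stage estimator: every
#' study gets its own intercept, covariate coefficients and treatment log-OR
#' `theta_j`; the `theta_j` are drawn from a normal population with mean
#' `theta_p` (the pooled effect) and SD `tau`.  Returns posterior draws,
#' medians and 95% equal-tailed credible intervals on the log-OR and OR
#' scales, plus split-R-hat and effective-sample-size diagnostics for every
#' parameter.  If any R-hat exceeds 1.05 or any ESS falls below 100 the
#' result carries a prominent non-convergence flag (and a warning); the
#' caller decides what to do with it.
#'
#' Chains are initialized at jittered Firth estimates of the study models;
#' warmup (equal to `iter`) is discarded and adaptation happens only during
#' warmup, so the retained chains are a valid MCMC sample.
#'
#' @param records Analytic records (exclusion-filtered and imputed).
#' @param contrast A [contrast_spec()] or its name.
#' @param covariates Adjustment set, as in [fit_study_logistic()].
#' @param priors A [prior_spec()].
#' @param chains Number of chains (at least 2).
#' @param iter Post-warmup iterations per chain (at least 1000).
#' @param seed Integer seed; chain c uses a fixed substream of it.
#' @return Object of class `bayes_summary`: `draws` (matrix, stacked chains
#'   by parameter), `medians`, `intervals` (data frame with log-OR and OR
#'   scale endpoints for the effect parameters), `diagnostics` (R-hat and
#'   ESS per parameter), `non_convergence`, `chains`, `iter`, `seed`.
#' @export
fit_bayes_hierarchical <- function(records, contrast,
                                   covariates = DEFAULT_COVARIATES,
                                   priors = prior_spec(), chains = 2L,
                                   iter = 2000L, seed = 1L) {
  if (chains < 2) stop_field("chains", "need at least 2 chains")
  if (iter < 1000) stop_field("iter", "need at least 1000 post-warmup iterations")
  if (!inherits(priors, "prior_spec")) stop_field("priors", "use prior_spec()")
  encs <- encode_eligible_studies(records, contrast, covariates)
  J <- length(encs)
  study_ids <- vapply(encs, `[[`, character(1), "study_id")

  # Split each design into nuisance columns Z and the treatment vector.
  # All non-intercept columns are mean-centered for sampling: a linear
  # reparametrization that leaves every coefficient except the intercept
  # unchanged and decorrelates the scalar updates.
  studies <- lapply(encs, function(e) {
    k <- match("treat", colnames(e$X))
    Z <- e$X[, -k, drop = FALSE]
    for (cc in seq_len(ncol(Z))[-1]) Z[, cc] <- Z[, cc] - mean(Z[, cc])
    treat_c <- e$treat - mean(e$treat)
    init <- logit_firth(cbind(Z, treat = treat_c), e$y)$coef
    list(Z = Z, treat = treat_c, y = e$y,
         init = c(init[seq_len(ncol(Z))], init[ncol(Z) + 1L]),
         k = ncol(Z) + 1L, znames = colnames(e$X)[-k])
  })

  par_names <- c("theta_p", "tau", paste0("theta_", study_ids),
                 unlist(lapply(seq_len(J), function(j) {
                   paste0(study_ids[j], ":", studies[[j]]$znames)
                 })))
  npar <- length(par_names)

  chain_draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(substream_seed(seed, 500L + ch))
    chain_draws[[ch]] <- run_hier_chain(studies, priors, iter, npar)
  }
  for (ch in seq_len(chains)) colnames(chain_draws[[ch]]) <- par_names

  diagnostics <- mcmc_diagnostics(chain_draws)
  non_conv <- any(diagnostics$rhat > 1.05, na.rm = TRUE) ||
    any(diagnostics$ess < 100, na.rm = TRUE)
  if (non_conv) {
    warning("MCMC non-convergence: some R-hat > 1.05 or ESS < 100",
            call. = FALSE)
  }
  draws <- do.call(rbind, chain_draws)
  effect_pars <- c("theta_p", paste0("theta_", study_ids))
  intervals <- do.call(rbind, lapply(effect_pars, function(p) {
    ci <- posterior_interval(draws[, p], 0.95)
    data.frame(parameter = p, median = stats::median(draws[, p]),
               lower = ci[1], upper = ci[2],
               or_median = exp(stats::median(draws[, p])),
               or_lower = exp(ci[1]), or_upper = exp(ci[2]),
               stringsAsFactors = FALSE)
  }))
  structure(
    list(draws = draws, medians = apply(draws, 2, stats::median),
         intervals = intervals, diagnostics = diagnostics,
         non_convergence = non_conv, chains = chains, iter = iter,
         seed = seed, priors = priors, study_ids = study_ids),
    class = "bayes_summary"
  )
}

run_hier_chain <- function(studies, priors, iter, npar) {
  J <- length(studies)
  # State, initialized at jittered penalized estimates.
  gamma <- lapply(studies, function(s) {
    s$init[-s$k] + stats::rnorm(length(s$init) - 1L, 0, 0.1)
  })
  theta <- vapply(studies, function(s) s$init[s$k] + stats::rnorm(1, 0, 0.1),
                  numeric(1))
  theta_p <- mean(theta)
  tau <- 0.5
  eta <- lapply(seq_len(J), function(j) {
    drop(studies[[j]]$Z %*% gamma[[j]]) + studies[[j]]$treat * theta[j]
  })
  ll <- vapply(seq_len(J), function(j) {
    bernoulli_loglik(eta[[j]], studies[[j]]$y)
  }, numeric(1))

  n_scalar <- sum(vapply(gamma, length, integer(1))) + J + 1L  # + tau
  prop_sd <- rep(0.2, n_scalar)
  acc <- integer(n_scalar)
  adapt_block <- 50L

  total <- 2L * iter  # warmup = iter
  out <- matrix(NA_real_, iter, npar)
  row <- 0L
  for (it in seq_len(total)) {
    p_idx <- 0L
    for (j in seq_len(J)) {
      s <- studies[[j]]
      # Nuisance coefficients.
      for (k in seq_along(gamma[[j]])) {
        p_idx <- p_idx + 1L
        d <- stats::rnorm(1, 0, prop_sd[p_idx])
        eta_new <- eta[[j]] + s$Z[, k] * d
        ll_new <- bernoulli_loglik(eta_new, s$y)
        g <- gamma[[j]][k]
        logr <- ll_new - ll[j] +
          stats::dnorm(g + d, 0, priors$sd_nuisance, log = TRUE) -
          stats::dnorm(g, 0, priors$sd_nuisance, log = TRUE)
        if (log(stats::runif(1)) < logr) {
          gamma[[j]][k] <- g + d
          eta[[j]] <- eta_new
          ll[j] <- ll_new
          acc[p_idx] <- acc[p_idx] + 1L
        }
      }
      # Study treatment effect.
      p_idx <- p_idx + 1L
      d <- stats::rnorm(1, 0, prop_sd[p_idx])
      eta_new <- eta[[j]] + s$treat * d
      ll_new <- bernoulli_loglik(eta_new, s$y)
      tau_safe <- max(tau, 1e-8)
      logr <- ll_new - ll[j] +
        stats::dnorm(theta[j] + d, theta_p, tau_safe, log = TRUE) -
        stats::dnorm(theta[j], theta_p, tau_safe, log = TRUE)
      if (log(stats::runif(1)) < logr) {
        theta[j] <- theta[j] + d
        eta[[j]] <- eta_new
        ll[j] <- ll_new
        acc[p_idx] <- acc[p_idx] + 1L
      }
    }
    # Conjugate update for the pooled effect.
    tau_safe <- max(tau, 1e-8)
    prec <- J / tau_safe^2 + 1 / priors$sd_pooled_effect^2
    theta_p <- stats::rnorm(1, (sum(theta) / tau_safe^2) / prec,
                            sqrt(1 / prec))
    # Between-study SD on the log scale (half-normal prior + Jacobian).
    # tau's conditional involves only J normal densities, so several cheap
    # updates per sweep keep its autocorrelation comparable to the rest.
    p_idx <- p_idx + 1L
    logpost <- function(t) {
      sum(stats::dnorm(theta, theta_p, t, log = TRUE)) +
        stats::dnorm(t, 0, priors$scale_tau, log = TRUE) + log(t)
    }
    for (rep_tau in 1:5) {
      tau_safe <- max(tau, 1e-8)
      d <- stats::rnorm(1, 0, prop_sd[p_idx])
      tau_new <- exp(log(tau_safe) + d)
      if (log(stats::runif(1)) < logpost(tau_new) - logpost(tau_safe)) {
        tau <- tau_new
        acc[p_idx] <- acc[p_idx] + 1L
      }
    }
    # Adapt during warmup only.
    if (it <= iter && it %% adapt_block == 0L) {
      rate <- acc / adapt_block
      rate[n_scalar] <- rate[n_scalar] / 5  # tau gets 5 updates per sweep
      prop_sd <- pmin(pmax(prop_sd * exp(rate - 0.3), 1e-3), 5)
      acc[] <- 0L
    }
    if (it > iter) {
      row <- row + 1L
      out[row, ] <- c(theta_p, tau, theta,
                      unlist(gamma, use.names = FALSE))
    }
  }
  out
}

#' @export
print.bayes_summary <- function(x, ...) {
  cat(sprintf("Bayesian hierarchical model (%d chains x %d iterations)\n",
              x$chains, x$iter))
  df <- x$intervals
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-14s median %7.3f, 95%% CrI [%7.3f, %7.3f]  (OR %.2f [%.2f, %.2f])\n",
                df$parameter[i], df$median[i], df$lower[i], df$upper[i],
                df$or_median[i], df$or_lower[i], df$or_upper[i]))
  }
  cat(sprintf("  max R-hat %.3f, min ESS %.0f%s\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess),
              if (x$non_convergence) "  ** NON-CONVERGENCE **" else ""))
  invisible(x)
}

#' Normal-likelihood pooling model for study summaries
#'
#' Replaces the participant-level likelihood with fixed study summaries
#' \eqn{\hat\theta_j \sim N(\theta_j, v_j)}, with the between-study SD `tau`
#' held fixed.  With `tau = 0` all study effects equal the pooled effect and
#' (under a flat or very wide prior) the posterior of `theta_p` is the
#' conjugate normal centered at the inverse-variance pooled estimate — the
#' closed-form limit used to validate the MCMC machinery.  With zero studies
#' the posterior is the prior.  Sampling is by the same adaptive random-walk
#' scheme as the hierarchical model.
#'
#' @param theta_hat Study log-OR estimates (possibly length 0 for a
#'   prior-only run).
#' @param variance Their variances.
#' @param priors A [prior_spec()]; `sd_pooled_effect = Inf` gives a flat
#'   prior (only allowed with at least one study).
#' @param tau Fixed between-study SD (default 0).
#' @param chains,iter,seed As in [fit_bayes_hierarchical()].
#' @return Object of class `bayes_summary` with draws of `theta_p` (and
#'   `theta_j` when `tau > 0`).
#' @export
bayes_pool_normal <- function(theta_hat, variance, priors = prior_spec(),
                              tau = 0, chains = 2L, iter = 5000L, seed = 1L) {
  if (chains < 2) stop_field("chains", "need at least 2 chains")
  J <- length(theta_hat)
  if (length(variance) != J) stop_field("variance", "length mismatch")
  if (J > 0 && (any(!is.finite(variance)) || any(variance <= 0))) {
    stop_field("variance", "must be positive")
  }
  if (J == 0 && !is.finite(priors$sd_pooled_effect)) {
    stop_field("priors", "prior-only run needs a proper (finite) prior")
  }
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0) {
    stop_field("tau", "must be a nonnegative scalar")
  }
  sd0 <- priors$sd_pooled_effect
  se_j <- sqrt(variance)

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    theta_p <- stats::rnorm(1, 0, 0.5)
    theta <- rep(theta_p, J)
    prop_sd <- 0.5
    acc <- 0L
    total <- 2L * iter
    keep <- matrix(NA_real_, iter, 1L + if (tau > 0) J else 0L)
    row <- 0L
    logpost_tp <- function(tp, th) {
      lp <- if (is.finite(sd0)) stats::dnorm(tp, 0, sd0, log = TRUE) else 0
      if (J == 0) return(lp)
      if (tau > 0) {
        lp + sum(stats::dnorm(th, tp, tau, log = TRUE))
      } else {
        lp + sum(stats::dnorm(theta_hat, tp, se_j, log = TRUE))
      }
    }
    for (it in seq_len(total)) {
      if (tau > 0 && J > 0) {
        # Conjugate draw for each study effect given theta_p.
        post_prec <- 1 / variance + 1 / tau^2
        post_mean <- (theta_hat / variance + theta_p / tau^2) / post_prec
        theta <- stats::rnorm(J, post_mean, sqrt(1 / post_prec))
      }
      d <- stats::rnorm(1, 0, prop_sd)
      if (log(stats::runif(1)) < logpost_tp(theta_p + d, theta) -
            logpost_tp(theta_p, theta)) {
        theta_p <- theta_p + d
        acc <- acc + 1L
      }
      if (it <= iter && it %% 50L == 0L) {
        prop_sd <- pmin(pmax(prop_sd * exp(acc / 50 - 0.3), 1e-3), 50)
        acc <- 0L
      }
      if (it > iter) {
        row <- row + 1L
        keep[row, ] <- if (tau > 0) c(theta_p, theta) else theta_p
      }
    }
    keep
  }

  par_names <- c("theta_p", if (tau > 0) paste0("theta_", seq_len(J)))
  chain_draws <- lapply(seq_len(chains), function(ch) {
    m <- run_chain(substream_seed(seed, 700L + ch))
    colnames(m) <- par_names
    m
  })
  diagnostics <- mcmc_diagnostics(chain_draws)
  non_conv <- any(diagnostics$rhat > 1.05, na.rm = TRUE) ||
    any(diagnostics$ess < 100, na.rm = TRUE)
  draws <- do.call(rbind, chain_draws)
  intervals <- do.call(rbind, lapply(par_names, function(p) {
    ci <- posterior_interval(draws[, p], 0.95)
    data.frame(parameter = p, median = stats::median(draws[, p]),
               lower = ci[1], upper = ci[2],
               or_median = exp(stats::median(draws[, p])),
               or_lower = exp(ci[1]), or_upper = exp(ci[2]),
               stringsAsFactors = FALSE)
  }))
  structure(
    list(draws = draws, medians = apply(draws, 2, stats::median),
         intervals = intervals, diagnostics = diagnostics,
         non_convergence = non_conv, chains = chains, iter = iter,
         seed = seed, priors = priors, tau = tau),
    class = "bayes_summary"
  )
}

#' Equal-tailed posterior credible interval
#'
#' @param draws Numeric vector of at least 100 posterior draws.
#' @param level Interval mass in (0, 1).
#' @return Length-2 vector of the empirical `(1-level)/2` and
#'   `1-(1-level)/2` percentiles.  The OR-scale interval is the elementwise
#'   exponential of the log-scale one.
#' @export
posterior_interval <- function(draws, level = 0.95) {
  if (length(draws) == 0L) stop_field("draws", "no posterior draws")
  if (length(draws) < 100L) stop_field("draws", "need at least 100 draws")
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop_field("level", "must be in (0, 1)")
  }
  alpha <- (1 - level) / 2
  stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE)
}

# --- MCMC diagnostics: split R-hat and Geyer initial-sequence ESS ---------

split_chains <- function(chains) {
  out <- list()
  for (m in chains) {
    n <- nrow(m)
    half <- floor(n / 2)
    out <- c(out, list(m[seq_len(half), , drop = FALSE],
                       m[(n - half + 1):n, , drop = FALSE]))
  }
  out
}

rhat_one <- function(x_list) {
  n <- length(x_list[[1]])
  means <- vapply(x_list, mean, numeric(1))
  vars <- vapply(x_list, stats::var, numeric(1))
  W <- mean(vars)
  if (!is.finite(W) || W < 1e-12) return(1)
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_one <- function(x_list) {
  M <- length(x_list)
  N <- length(x_list[[1]])
  vars <- vapply(x_list, stats::var, numeric(1))
  W <- mean(vars)
  if (!is.finite(W) || W < 1e-12) return(M * N)
  means <- vapply(x_list, mean, numeric(1))
  B_over_n <- stats::var(means)
  var_plus <- (N - 1) / N * W + B_over_n
  lag_max <- min(N - 1L, 500L)
  acov <- vapply(x_list, function(x) {
    drop(stats::acf(x, lag.max = lag_max, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf)
  }, numeric(lag_max + 1L))
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov[-1]) / var_plus
  # Geyer initial positive sequence on paired autocorrelation sums:
  # tau = -1 + 2 * sum of pairs (1 + rho1), (rho2 + rho3), ... while positive.
  tau_sum <- 1 + rho[1]
  k <- 1L
  while (2L * k + 1L <= length(rho)) {
    pair <- rho[2L * k] + rho[2L * k + 1L]
    if (pair < 0) break
    tau_sum <- tau_sum + pair
    k <- k + 1L
  }
  tau_int <- max(-1 + 2 * tau_sum, 1e-3)
  M * N / tau_int
}

mcmc_diagnostics <- function(chains) {
  pars <- colnames(chains[[1]])
  halves <- split_chains(chains)
  data.frame(
    parameter = pars,
    rhat = vapply(seq_along(pars), function(p) {
      rhat_one(lapply(halves, function(m) m[, p]))
    }, numeric(1)),
    ess = vapply(seq_along(pars), function(p) {
      ess_one(lapply(halves, function(m) m[, p]))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}
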