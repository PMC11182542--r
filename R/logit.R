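# Logistic-regression internals: plain maximum likelihood by iteratively
# reweighted least squares with separation monitoring, and a Firth
# (Jeffreys-prior) penalized fit used as the fallback when the MLE diverges,
# so resampling replicates always return finite statistics.

logit_deviance <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  -2 * bernoulli_loglik(eta, y)
}

# Plain MLE path.  Separation is flagged when any coefficient exceeds 10 in
# absolute value along the path, when the deviance stops decreasing, or when
# the iteration cap is hit without convergence.
logit_irls <- function(X, y, max_iter = 100L, tol = 1e-8, coef_cap = 10) {
  p <- ncol(X)
  beta <- numeric(p)
  dev <- logit_deviance(X, y, beta)
  converged <- FALSE
  separated <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(drop(solve(XtW %*% X, XtW %*% z)),
                         error = function(e) NULL)
    if (is.null(beta_new) || any(!is.finite(beta_new))) {
      separated <- TRUE
      break
    }
    if (max(abs(beta_new)) > coef_cap) {
      beta <- beta_new
      separated <- TRUE
      break
    }
    dev_new <- logit_deviance(X, y, beta_new)
    # Newton can overshoot; halve the step before reading a non-decreasing
    # deviance as separation.
    halvings <- 0L
    while (dev_new > dev + 1e-6 && halvings < 10L) {
      beta_new <- (beta + beta_new) / 2
      dev_new <- logit_deviance(X, y, beta_new)
      halvings <- halvings + 1L
    }
    if (dev_new > dev + 1e-6) {
      separated <- TRUE
      break
    }
    done <- abs(dev - dev_new) / (abs(dev_new) + 0.1) < tol
    beta <- beta_new
    dev <- dev_new
    if (done) {
      converged <- TRUE
      break
    }
  }
  vcov <- NULL
  if (converged) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    vcov <- tryCatch(solve(crossprod(X * sqrt(w))), error = function(e) NULL)
    if (is.null(vcov)) {
      converged <- FALSE
      separated <- TRUE
    }
  }
  list(coef = beta, vcov = vcov, converged = converged,
       separated = separated, deviance = dev, iterations = it)
}

firth_penalized_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(X * sqrt(w))
  pen <- as.numeric(determinant(info, logarithm = TRUE)$modulus)
  if (!is.finite(pen)) return(-Inf)
  bernoulli_loglik(eta, y) + 0.5 * pen
}

# Firth fit via modified-score IRLS with step halving.  The penalized
# estimate is always finite, even under complete separation or a constant
# outcome.  Variance from the inverse Fisher information at the estimate.
logit_firth <- function(X, y, max_iter = 200L, tol = 1e-8) {
  p <- ncol(X)
  beta <- numeric(p)
  pl <- firth_penalized_loglik(X, y, beta)
  converged <- FALSE
  Iinv <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    Iinv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(Iinv)) {
      # Rank deficiency: ridge the information slightly and continue.
      Iinv <- solve(info + diag(1e-8, p))
    }
    h <- rowSums((XW %*% Iinv) * XW)
    score <- drop(t(X) %*% (y - mu + h * (0.5 - mu)))
    if (max(abs(score)) < 1e-6 && it > 1L) {
      converged <- TRUE
      break
    }
    step <- drop(Iinv %*% score)
    pl_new <- firth_penalized_loglik(X, y, beta + step)
    halvings <- 0L
    while (pl_new < pl - 1e-12 && halvings < 15L) {
      step <- step / 2
      pl_new <- firth_penalized_loglik(X, y, beta + step)
      halvings <- halvings + 1L
    }
    beta <- beta + step
    if (is.finite(pl_new) && is.finite(pl) && abs(pl_new - pl) < tol &&
        max(abs(step)) < 1e-6) {
      pl <- pl_new
      converged <- TRUE
      break
    }
    pl <- pl_new
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(X * sqrt(w))
  vcov <- tryCatch(solve(info), error = function(e) solve(info + diag(1e-8, p)))
  list(coef = beta, vcov = vcov, converged = converged,
       separated = FALSE, iterations = it)
}

# Unified entry: MLE first; Firth fallback on separation or non-convergence.
# Rank-deficient columns (constant or collinear, as can happen in bootstrap
# resamples) are dropped before fitting; their coefficients come back NA so
# the remaining indices stay aligned with X's columns.
fit_logit <- function(X, y) {
  p <- ncol(X)
  qrX <- qr(X)
  keep <- sort(qrX$pivot[seq_len(qrX$rank)])
  Xf <- if (length(keep) < p) X[, keep, drop = FALSE] else X
  fit <- logit_irls(Xf, y)
  penalized <- FALSE
  if (!fit$converged || fit$separated) {
    fit <- logit_firth(Xf, y)
    penalized <- TRUE
  }
  coef <- rep(NA_real_, p)
  vcov <- matrix(NA_real_, p, p)
  coef[keep] <- fit$coef
  vcov[keep, keep] <- fit$vcov
  list(coef = coef, vcov = vcov, converged = fit$converged,
       penalized = penalized)
}
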