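test_that("covariate encoding uses the documented column order and coding", {
  rec <- make_varied_study()
  enc <- encode_covariates(rec, contrast = "any_med")
  expect_identical(colnames(enc$X),
                   c("intercept", "treat", "age_c", "female", "race_White",
                     "race_Other", "unhoused", "stimulant"))
  # reference participant: ETAU, age at the study mean, male, White,
  # housed, no stimulant use
  expect_equal(mean(rec$age), 39)
  expect_equal(unname(enc$X[1, ]), c(1, 0, 0, 0, 1, 0, 0, 0))
  # race = Other -> (race_White, race_Other) = (0, 1)
  expect_equal(unname(enc$X[3, c("race_White", "race_Other")]), c(0, 1))
  expect_equal(enc$y, as.numeric(rec$outcome == "positive"))

  all_female <- rec
  all_female$sex <- "female"
  expect_warning(enc2 <- encode_covariates(all_female, contrast = "any_med"),
                 "single-level covariate")
  expect_false("female" %in% colnames(enc2$X))
  expect_identical(enc2$dropped, "female")
})

test_that("missing baseline covariates are imputed within study with warning", {
  rec <- make_varied_study()
  rec$age[2] <- NA
  rec$unhoused[3] <- NA
  expect_warning(expect_warning(
    enc <- encode_covariates(rec, contrast = "any_med"),
    "age"), "unhoused")
  expect_false(anyNA(enc$X))
})

test_that("a lone binary predictor recovers the crude log cross-ratio", {
  rec <- make_2x2_records(30, 10, 35, 5)
  est <- fit_study_logistic(rec, "any_med", covariates = NULL)
  expect_equal(est$theta_hat, crude_log_or(30, 10, 35, 5), tolerance = 1e-3)
  expect_equal(est$se, woolf_se(30, 10, 35, 5), tolerance = 1e-3)
  expect_equal(est$n_treated, 40)
  expect_equal(est$n_reference, 40)
  expect_false(est$penalized)

  sym <- make_2x2_records(20, 20, 20, 20)
  est_sym <- fit_study_logistic(sym, "any_med", covariates = NULL)
  expect_lt(abs(est_sym$theta_hat), 1e-8)
})

test_that("crude MLE equals the closed-form log cross-ratio on random tables", {
  set.seed(41)
  for (i in 1:50) {
    cells <- sample(1:50, 4, replace = TRUE)
    rec <- make_2x2_records(cells[1], cells[2], cells[3], cells[4])
    est <- fit_study_logistic(rec, "any_med", covariates = NULL)
    expect_equal(est$theta_hat, do.call(crude_log_or, as.list(cells)),
                 tolerance = 1e-6)
    expect_equal(est$variance, do.call(woolf_se, as.list(cells))^2,
                 tolerance = 1e-6)
  }
})

test_that("adjusted fits agree with glm on nondegenerate data", {
  cohort <- simulate_cohort(sim_config(
    seed = 33, missingness = list(mechanism = "MCAR", rate = 0)))
  for (s in unique(cohort$study_id)) {
    d <- cohort[cohort$study_id == s, ]
    est <- fit_study_logistic(d, "any_med")
    g <- stats::glm(
      I(outcome == "positive") ~ I(arm != "ETAU") + I(age - mean(age)) +
        I(sex == "female") + I(race == "White") + I(race == "Other") +
        unhoused + stimulant_use,
      data = d, family = stats::binomial())
    expect_equal(est$theta_hat, unname(stats::coef(g)[2]), tolerance = 1e-5)
    expect_equal(est$se, sqrt(stats::vcov(g)[2, 2]), tolerance = 1e-4)
  }
})

test_that("separation triggers a finite Firth fit with the penalized flag", {
  rec <- make_2x2_records(15, 0, 8, 7)  # treated arm all positive
  est <- fit_study_logistic(rec, "any_med", covariates = NULL)
  expect_true(est$penalized)
  expect_true(is.finite(est$theta_hat))
  expect_true(est$variance > 0)
  # Firth on a 2x2 equals the log cross-ratio with 0.5 added to each cell
  expect_equal(est$theta_hat,
               log((15.5 * 7.5) / (0.5 * 8.5)), tolerance = 1e-4)
})

test_that("study fit errors are explicit for missing arms and constant outcomes", {
  rec <- make_2x2_records(5, 5, 5, 5)
  only_etau <- rec[rec$arm == "ETAU", ]
  expect_error(fit_study_logistic(only_etau, "any_med", NULL), "lacks")
  expect_error(fit_study_logistic(rec, "pn", NULL), "lacks")
  const <- rec
  const$outcome <- "positive"
  expect_error(fit_study_logistic(const, "any_med", NULL), "single level")
})

test_that("inverse-variance pooling matches hand-computed values", {
  single <- pool_estimates(data.frame(study_id = "a", theta_hat = 0.7,
                                      variance = 0.09))
  expect_equal(single$theta_p, 0.7)
  expect_equal(single$se_p, 0.3)

  two <- pool_estimates(data.frame(study_id = c("a", "b"),
                                   theta_hat = c(0.5, -0.3),
                                   variance = c(0.04, 0.01)))
  expect_equal(unname(two$weights), c(25, 100))
  expect_equal(two$theta_p, -0.14)
  expect_equal(two$se_p, sqrt(1 / 125))
  expect_equal(two$odds_ratio, exp(-0.14))

  const3 <- pool_estimates(data.frame(study_id = c("a", "b", "c"),
                                      theta_hat = rep(-0.4, 3),
                                      variance = c(0.3, 0.01, 2)))
  expect_equal(const3$theta_p, -0.4)

  expect_error(pool_estimates(list()), "at least one")
  expect_error(pool_estimates(data.frame(study_id = "a", theta_hat = 1,
                                         variance = 0)), "'a'")
})

test_that("pooling is order- and scale-invariant and stays in the convex hull", {
  set.seed(99)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    df <- data.frame(study_id = paste0("s", 1:k),
                     theta_hat = stats::rnorm(k),
                     variance = stats::runif(k, 0.01, 1))
    p1 <- pool_estimates(df)
    p2 <- pool_estimates(df[sample(k), ])
    expect_equal(p1$theta_p, p2$theta_p)
    # rescaling all variances by c rescales weights but not the estimate
    p3 <- pool_estimates(transform(df, variance = variance * 3.7))
    expect_equal(p1$theta_p, p3$theta_p)
    expect_gte(p1$theta_p, min(df$theta_hat) - 1e-12)
    expect_lte(p1$theta_p, max(df$theta_hat) + 1e-12)
  }
})

test_that("pooling agrees with a fixed-effect meta-analysis fit", {
  df <- data.frame(study_id = c("a", "b", "c"),
                   theta_hat = c(0.34, -0.58, -1.34),
                   variance = c(0.233, 0.453, 0.218))
  own <- pool_estimates(df)
  fe <- metafor::rma(yi = df$theta_hat, vi = df$variance, method = "FE")
  expect_equal(own$theta_p, unname(fe$beta[1, 1]), tolerance = 1e-10)
  expect_equal(own$se_p, unname(fe$se), tolerance = 1e-10)
})

test_that("pooled-estimate bias shrinks as per-arm sample size grows", {
  r1 <- recovery_sim(theta = log(0.67), n_scale = 1L, n_reps = 150L, seed = 61)
  r10 <- recovery_sim(theta = log(0.67), n_scale = 10L, n_reps = 150L, seed = 61)
  bias1 <- abs(r1$mean_theta_p - log(0.67))
  bias10 <- abs(r10$mean_theta_p - log(0.67))
  expect_lt(bias10, bias1 + 0.02)
  expect_lt(bias10, 0.05)
})
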