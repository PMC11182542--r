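test_that("design and config validation names the offending field", {
  expect_error(study_design("s", n_med = 0, n_etau = 10), "arm_sizes")
  expect_error(study_design("", n_med = 5, n_etau = 5), "study_id")
  expect_error(design_registry(list()), "designs")
  expect_error(
    sim_config(study_intercepts = c(0, 0)),  # three designs by default
    "study_intercepts")
  expect_error(
    sim_config(covariate_distributions = modifyList(
      default_covariate_distributions(),
      list(race = c(Black = 0.6, White = 0.6, Other = 0.1)))),
    "race")
  expect_error(
    sim_config(exclusion_rates = c(prison_transfer = 0.6,
                                   incarcerated_at_followup = 0.6,
                                   deceased = 0)),
    "exclusion_rates")
  expect_error(
    sim_config(missingness = list(mechanism = "MNAR", rate = 0.1)),
    "mechanism")
})

test_that("cohort generation respects designs and is deterministic", {
  cfg <- sim_config(seed = 9)
  rec <- generate_cohort(cfg)
  expect_equal(nrow(rec), 330)
  tab <- table(rec$study_id, rec$arm)
  expect_equal(unname(tab["site1", c("ETAU", "MED")]), c(52, 58))
  expect_equal(unname(tab["site2", c("ETAU", "MED", "MED_PN")]), c(19, 29, 21))
  expect_equal(unname(tab["site3", c("ETAU", "MED", "MED_PN")]), c(51, 46, 54))
  expect_true(all(rec$medication_type[rec$arm == "ETAU"] == "none"))
  expect_true(all(rec$medication_type[rec$study_id == "site3" &
                                        rec$arm != "ETAU"] == "IM"))
  expect_identical(rec, generate_cohort(sim_config(seed = 9)))
  expect_false(identical(rec, generate_cohort(sim_config(seed = 10))))
})

test_that("covariate marginals converge to the configured distributions", {
  big <- sim_config(
    designs = list(study_design("big", n_med = 5000, n_etau = 5000)),
    study_intercepts = 0, theta_med = 0, seed = 77)
  rec <- generate_cohort(big)
  n <- nrow(rec)
  cd <- default_covariate_distributions()
  for (nm in c("female", "hispanic", "unhoused", "stimulant_use")) {
    p <- cd[[nm]]
    obs <- switch(nm, female = mean(rec$sex == "female"),
                  hispanic = mean(rec$hispanic),
                  unhoused = mean(rec$unhoused),
                  stimulant_use = mean(rec$stimulant_use))
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
  }
  for (r in names(cd$race)) {
    p <- cd$race[[r]]
    expect_lt(abs(mean(rec$race == r) - p), 3 * sqrt(p * (1 - p) / n))
  }
  # Age targets the truncated-normal mean on [18, 80].
  a <- (cd$age$min - cd$age$mean) / cd$age$sd
  b <- (cd$age$max - cd$age$mean) / cd$age$sd
  trunc_mean <- cd$age$mean + cd$age$sd * (dnorm(a) - dnorm(b)) /
    (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(rec$age) - trunc_mean), 4 * cd$age$sd / sqrt(n))
  expect_true(all(rec$age >= 18 & rec$age <= 80))
})

test_that("generated outcomes follow the configured logistic model", {
  flat_effects <- setNames(rep(0, 6), names(default_covariate_effects()))
  null_cfg <- sim_config(
    designs = list(study_design("s", n_med = 10000, n_etau = 10000)),
    study_intercepts = 0, theta_med = 0,
    covariate_effects = flat_effects, seed = 5)
  rec <- generate_cohort(null_cfg)
  for (a in c("ETAU", "MED")) {
    frac <- mean(rec$outcome[rec$arm == a] == "positive")
    expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  }

  or_cfg <- sim_config(
    designs = list(study_design("s", n_med = 50000, n_etau = 50000)),
    study_intercepts = 0, theta_med = log(3),
    covariate_effects = flat_effects, seed = 6)
  rec <- generate_cohort(or_cfg)
  pt <- mean(rec$outcome[rec$arm == "MED"] == "positive")
  pr <- mean(rec$outcome[rec$arm == "ETAU"] == "positive")
  emp_or <- (pt / (1 - pt)) / (pr / (1 - pr))
  expect_lt(abs(emp_or - 3) / 3, 0.05)
})

test_that("follow-up process applies exclusion and missingness rates", {
  cfg0 <- sim_config(seed = 3, missingness = list(mechanism = "MCAR", rate = 0))
  rec <- generate_cohort(cfg0)
  out <- apply_followup_process(rec, cfg0)
  expect_true(all(out$follow_up_status == "in_community"))
  expect_identical(out$outcome, rec$outcome)

  cfg <- sim_config(
    designs = list(study_design("s", n_med = 5000, n_etau = 5000)),
    study_intercepts = 0, theta_med = 0,
    missingness = list(mechanism = "MCAR", rate = 0.2), seed = 8)
  out <- simulate_cohort(cfg)
  expect_lt(abs(mean(out$outcome == "missing") - 0.2), 0.01)

  # Prison-transfer rate calibrated to an expected 48 exclusions among 488
  # enrolled (the published participant flow).
  cfg_excl <- sim_config(
    designs = list(study_design("s", n_med = 244, n_etau = 244)),
    study_intercepts = 0, theta_med = 0,
    missingness = list(mechanism = "MCAR", rate = 0),
    exclusion_rates = c(prison_transfer = 48 / 488,
                        incarcerated_at_followup = 0, deceased = 0),
    seed = 12)
  out <- simulate_cohort(cfg_excl)
  n_pt <- sum(out$follow_up_status == "prison_transfer")
  expect_lt(abs(n_pt - 48), 3 * sqrt(488 * (48 / 488) * (1 - 48 / 488)))

  expect_error(
    sim_config(exclusion_rates = c(prison_transfer = 0.5,
                                   incarcerated_at_followup = 0.4,
                                   deceased = 0.2)),
    "at most 1")
})

test_that("outcome-dependent missingness shifts with the latent outcome", {
  cfg <- sim_config(
    designs = list(study_design("s", n_med = 8000, n_etau = 8000)),
    study_intercepts = 0, theta_med = 0,
    missingness = list(mechanism = "outcome_dependent", rate = 0.15,
                       logit_shift = 1.0),
    seed = 21)
  rec <- generate_cohort(cfg)
  out <- apply_followup_process(rec, cfg)
  latent_pos <- rec$outcome == "positive"
  miss_pos <- mean(out$outcome[latent_pos] == "missing")
  miss_neg <- mean(out$outcome[!latent_pos] == "missing")
  expect_gt(miss_pos, miss_neg + 0.05)
  expect_lt(abs(miss_neg - 0.15), 0.02)
})

test_that("true pooled log-OR is the weighted average of study effects", {
  cfg3 <- sim_config(theta_med = c(-0.4, -0.4, -0.4))
  expect_equal(true_pooled_log_or(cfg3)$theta_p_true, -0.4)

  cfg2 <- sim_config(
    designs = list(study_design("a", 25, 25), study_design("b", 50, 50)),
    study_intercepts = c(0, 0), theta_med = c(0.5, -0.3))
  tp <- true_pooled_log_or(cfg2, weights = c(25, 100))
  expect_equal(tp$theta_p_true, -0.14)
  expect_equal(unname(tp$theta_j_true), c(0.5, -0.3))

  cfg1 <- sim_config(designs = list(study_design("only", 30, 30)),
                     study_intercepts = 0, theta_med = 0.7)
  expect_equal(true_pooled_log_or(cfg1)$theta_p_true, 0.7)
  expect_error(true_pooled_log_or(cfg1, weights = -1), "weights")
})
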