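test_that("exclusions remove non-community statuses and report counts", {
  rec <- make_2x2_records(3, 3, 2, 2)
  rec$follow_up_status <- c("in_community", "in_community", "prison_transfer",
                            "in_community", "in_community", "prison_transfer",
                            "incarcerated_at_followup", "in_community",
                            "deceased", "in_community")
  res <- apply_exclusions(rec)
  expect_equal(nrow(res$records), 6)
  expect_true(all(res$records$follow_up_status == "in_community"))
  # input order preserved among kept records
  expect_identical(res$records$participant_id,
                   rec$participant_id[rec$follow_up_status == "in_community"])
  counts <- setNames(res$report$counts$n, res$report$counts$reason)
  expect_equal(counts[["PRISON_TRANSFER"]], 2)
  expect_equal(counts[["INCARCERATED"]], 1)
  expect_equal(counts[["DECEASED"]], 1)
  expect_equal(res$report$n_input, res$report$n_kept +
                 length(res$report$excluded_ids))

  all_in <- make_2x2_records(3, 3, 2, 2)
  res2 <- apply_exclusions(all_in)
  expect_identical(res2$records, all_in)
  expect_equal(nrow(res2$report$counts), 0)

  bad <- all_in
  bad$follow_up_status[4] <- NA
  expect_error(apply_exclusions(bad), bad$participant_id[4], fixed = TRUE)
})

test_that("missing outcomes are imputed positive, observed untouched", {
  rec <- make_2x2_records(6, 9, 4, 1)  # 20 records, 10 positive
  rec$outcome[c(2, 8, 13, 17, 20)] <- "missing"
  pre_pos <- sum(rec$outcome == "positive")
  out <- impute_missing_as_positive(rec)
  expect_equal(sum(out$outcome == "positive"), pre_pos + 5)
  expect_true(all(out$imputed[c(2, 8, 13, 17, 20)]))
  expect_false(any(out$imputed[-c(2, 8, 13, 17, 20)]))
  expect_identical(out$outcome[rec$outcome == "negative"],
                   rec$outcome[rec$outcome == "negative"])

  # contract violation: a non-community record must not reach imputation
  bad <- rec
  bad$follow_up_status[1] <- "prison_transfer"
  expect_error(impute_missing_as_positive(bad), "contract violation")
})

test_that("imputation raises prevalence and the pipeline order is idempotent", {
  cfg <- sim_config(seed = 14,
                    exclusion_rates = c(prison_transfer = 0.08,
                                        incarcerated_at_followup = 0.2,
                                        deceased = 0.01))
  cohort <- simulate_cohort(cfg)
  step1 <- apply_exclusions(cohort)
  cc_prev <- mean(step1$records$outcome[step1$records$outcome != "missing"] ==
                    "positive")
  analytic <- impute_missing_as_positive(step1$records)
  expect_gt(mean(analytic$outcome == "positive"), cc_prev)

  # second pass changes nothing
  again <- impute_missing_as_positive(apply_exclusions(analytic)$records)
  expect_identical(again, analytic)

  # equality iff nothing was missing
  clean <- simulate_cohort(sim_config(
    seed = 15, missingness = list(mechanism = "MCAR", rate = 0)))
  expect_identical(impute_missing_as_positive(clean)$outcome, clean$outcome)
})

test_that("baseline summary reproduces count/percent/mean-SD arithmetic", {
  # 122 control with 28 female, 208 treated with 42 female -> 70 (21.2%)
  rec <- rbind(
    make_2x2_records(61, 61, 0, 1)[1:122, ],
    make_2x2_records(104, 104, 0, 1)[1:208, ])
  rec$participant_id <- sprintf("p%03d", seq_len(nrow(rec)))
  rec$arm <- c(rep("ETAU", 122), rep("MED", 208))
  rec$medication_type <- ifelse(rec$arm == "ETAU", "none", "XR-NTX")
  rec$sex <- "male"
  rec$sex[c(1:28, 123:164)] <- "female"
  bs <- summarize_baseline(rec)
  get_count <- function(group, var, level) {
    cc <- bs$groups[[group]]$categorical
    cc[cc$variable == var & cc$level == level, c("count", "percent")]
  }
  expect_equal(get_count("ETAU", "sex", "female")$count, 28)
  expect_equal(get_count("ETAU", "sex", "female")$percent, 23.0)
  expect_equal(get_count("any_treatment", "sex", "female")$count, 42)
  expect_equal(get_count("any_treatment", "sex", "female")$percent, 20.2)
  expect_equal(get_count("overall", "sex", "female")$count, 70)
  expect_equal(get_count("overall", "sex", "female")$percent, 21.2)
  expect_equal(bs$groups$overall$n,
               bs$groups$ETAU$n + bs$groups$any_treatment$n)

  # percentages over exhaustive categories sum to 100
  for (g in names(bs$groups)) {
    cc <- bs$groups[[g]]$categorical
    sums <- tapply(cc$percent, cc$variable, sum)
    expect_true(all(abs(sums - 100) <= 0.1))
  }
})

test_that("degenerate single-record group reports SD 0 with a warning", {
  rec <- make_2x2_records(1, 0, 1, 0)
  rec$age <- c(40, 35)
  # both single-record groups warn
  expect_warning(expect_warning(bs <- summarize_baseline(rec), "degenerate"),
                 "degenerate")
  expect_equal(bs$groups$any_treatment$continuous$mean, 40.0)
  expect_equal(bs$groups$any_treatment$continuous$sd, 0.0)

  all_female <- make_2x2_records(2, 2, 2, 2)
  all_female$sex <- "female"
  bs2 <- summarize_baseline(all_female)
  cc <- bs2$groups$overall$categorical
  expect_equal(cc[cc$variable == "sex", "percent"], 100.0)
})

test_that("cohort CSV round-trips losslessly and validates on read", {
  cohort <- simulate_cohort(sim_config(seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohort, path)
  back <- read_cohort_csv(path)
  expect_equal(back, cohort, tolerance = 1e-12)

  # invariant violation: control arm with a medication type
  bad <- cohort
  bad$medication_type[bad$arm == "ETAU"][1] <- "XR-NTX"
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_cohort_csv(path2), "medication_type")

  # extra column: error in strict mode, warning otherwise
  extra <- cohort
  extra$scratch <- 1
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(extra, path3, row.names = FALSE)
  expect_error(read_cohort_csv(path3), "unknown column")
  expect_warning(ok <- read_cohort_csv(path3, strict = FALSE), "ignoring")
  expect_false("scratch" %in% names(ok))

  # missing required column
  trunc <- cohort[, setdiff(cohort_columns(), "outcome")]
  path4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(trunc, path4, row.names = FALSE)
  expect_error(read_cohort_csv(path4), "outcome")
})
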