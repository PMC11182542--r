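# Builders for small in-code fixtures.

# A one-study cohort from 2x2 counts: treated/reference positives and
# negatives, constant covariates (use covariates = NULL when fitting).
make_2x2_records <- function(t_pos, t_neg, r_pos, r_neg, study = "s1",
                             treated_arm = "MED", reference_arm = "ETAU") {
  n <- t_pos + t_neg + r_pos + r_neg
  arm <- c(rep(treated_arm, t_pos + t_neg), rep(reference_arm, r_pos + r_neg))
  outcome <- c(rep("positive", t_pos), rep("negative", t_neg),
               rep("positive", r_pos), rep("negative", r_neg))
  data.frame(
    participant_id = sprintf("%s_%03d", study, seq_len(n)),
    study_id = study,
    arm = arm,
    medication_type = ifelse(arm == "ETAU", "none", "XR-NTX"),
    age = 40,
    sex = "male",
    race = "Black",
    hispanic = FALSE,
    unhoused = FALSE,
    stimulant_use = FALSE,
    follow_up_status = "in_community",
    outcome = outcome,
    imputed = FALSE,
    stringsAsFactors = FALSE
  )
}

# A small mixed-covariate study for encoding tests: both sexes, all races,
# housed/unhoused, stimulant yes/no, two arms.
make_varied_study <- function(study = "s1") {
  data.frame(
    participant_id = sprintf("%s_%03d", study, 1:8),
    study_id = study,
    arm = c("ETAU", "ETAU", "ETAU", "ETAU", "MED", "MED", "MED", "MED"),
    medication_type = c(rep("none", 4), rep("XR-NTX", 4)),
    age = c(39, 37, 41, 39, 35, 43, 39, 39),
    sex = c("male", "female", "male", "female", "male", "female", "male", "male"),
    race = c("White", "Black", "Other", "Black", "White", "Black", "Other", "Black"),
    hispanic = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    unhoused = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
    stimulant_use = c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    follow_up_status = "in_community",
    outcome = c("positive", "negative", "positive", "negative",
                "negative", "positive", "negative", "positive"),
    imputed = FALSE,
    stringsAsFactors = FALSE
  )
}

# Crude log cross-ratio and Woolf variance for a 2x2 table.
crude_log_or <- function(t_pos, t_neg, r_pos, r_neg) {
  log((t_pos * r_neg) / (t_neg * r_pos))
}
woolf_se <- function(t_pos, t_neg, r_pos, r_neg) {
  sqrt(1 / t_pos + 1 / t_neg + 1 / r_pos + 1 / r_neg)
}
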