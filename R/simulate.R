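#' Simulation configuration for multi-site trial cohorts
#'
#' Bundles everything the cohort generator needs: the per-study designs, the
#' generative logistic outcome model (study intercepts, treatment log-odds
#' ratios, covariate effects), covariate sampling distributions, the
#' missingness mechanism at follow-up, and the post-randomization exclusion
#' rates.  Defaults emulate a three-site jail-based collaborative: control-arm
#' outcome prevalence near 75%, a medication-vs-control conditional log-OR of
#' log(0.67), a navigation-vs-medication log-OR of log(0.61) where a
#' navigation arm exists, and covariate marginals matching the published
#' baseline table (mean age 39.2, 21.2% female, 49.1/40.9/10.0% Black/White/
#' Other, 31.9% unhoused).
#'
#' The treatment effects are placed on the conditional (covariate-adjusted)
#' log-odds scale, i.e. the same estimand the adjusted logistic model
#' estimates; because the odds ratio is noncollapsible, crude and conditional
#' values differ by design.
#'
#' @param designs List of [study_design()] objects.
#' @param study_intercepts Numeric, one per design: baseline (control-arm)
#'   log-odds of a positive outcome at covariate reference values.
#' @param theta_med Numeric, one per design: conditional log-OR for any
#'   medication arm vs control.
#' @param theta_pn Numeric, one per design: conditional log-OR for
#'   medication-plus-navigation vs medication alone; must be `NA` for designs
#'   without a navigation arm and finite for designs with one.
#' @param covariate_effects Named numeric vector of log-odds coefficients for
#'   `age` (per year, centered at the configured mean), `female`,
#'   `race_White`, `race_Other`, `unhoused`, `stimulant_use`.
#' @param covariate_distributions List with elements `age` (list
#'   `mean`, `sd`, `min`, `max`), `female`, `hispanic`, `unhoused`,
#'   `stimulant_use` (prevalences) and `race` (named probabilities over
#'   Black/White/Other summing to 1).
#' @param missingness List: `mechanism` (`"MCAR"` or `"outcome_dependent"`),
#'   `rate` (marginal missingness probability among in-community follow-ups)
#'   and, for the outcome-dependent mechanism, `logit_shift` (added to the
#'   logit of `rate` when the latent outcome is positive).
#' @param exclusion_rates Named probabilities for `prison_transfer`,
#'   `incarcerated_at_followup` and `deceased`; must sum to at most 1.
#' @param seed Integer root seed; all per-study substreams derive from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()], [apply_followup_process()], [simulate_cohort()]
#' @export
sim_config <- function(designs = default_designs(),
                       study_intercepts = rep(0.75, length(designs)),
                       theta_med = rep(log(0.67), length(designs)),
                       theta_pn = NULL,
                       covariate_effects = default_covariate_effects(),
                       covariate_distributions = default_covariate_distributions(),
                       missingness = list(mechanism = "MCAR", rate = 0.2),
                       exclusion_rates = c(prison_transfer = 0,
                                           incarcerated_at_followup = 0,
                                           deceased = 0),
                       seed = 1L) {
  designs <- validate_designs(designs)
  J <- length(designs)
  has_pn <- vapply(designs, `[[`, logical(1), "has_pn_arm")
  if (is.null(theta_pn)) {
    theta_pn <- ifelse(has_pn, log(0.61), NA_real_)
  }
  if (length(study_intercepts) != J || !is.numeric(study_intercepts) ||
      any(!is.finite(study_intercepts))) {
    stop_field("study_intercepts", "need one finite intercept per design")
  }
  if (length(theta_med) != J || !is.numeric(theta_med) ||
      any(!is.finite(theta_med))) {
    stop_field("theta_med", "need one finite treatment log-OR per design")
  }
  if (length(theta_pn) != J) {
    stop_field("theta_pn", "need one value per design (NA where no PN arm)")
  }
  if (any(has_pn & !is.finite(theta_pn))) {
    stop_field("theta_pn", "must be finite for designs with a PN arm")
  }

  eff_names <- c("age", "female", "race_White", "race_Other", "unhoused",
                 "stimulant_use")
  if (!is.numeric(covariate_effects) ||
      !all(eff_names %in% names(covariate_effects))) {
    stop_field("covariate_effects",
               paste("must be a named numeric vector covering",
                     paste(eff_names, collapse = ", ")))
  }
  covariate_effects <- covariate_effects[eff_names]
  if (any(!is.finite(covariate_effects))) {
    stop_field("covariate_effects", "coefficients must be finite")
  }

  cd <- covariate_distributions
  for (nm in c("age", "female", "hispanic", "unhoused", "stimulant_use", "race")) {
    if (is.null(cd[[nm]])) stop_field("covariate_distributions",
                                      sprintf("missing element `%s`", nm))
  }
  if (!is.list(cd$age) || !is.finite(cd$age$mean) || !is.finite(cd$age$sd) ||
      cd$age$sd <= 0) {
    stop_field("covariate_distributions$age", "needs finite mean and positive sd")
  }
  for (nm in c("female", "hispanic", "unhoused", "stimulant_use")) {
    assert_probability(cd[[nm]], paste0("covariate_distributions$", nm))
  }
  race <- cd$race
  if (!all(RACE_LEVELS %in% names(race))) {
    stop_field("covariate_distributions$race",
               "must name probabilities for Black, White, Other")
  }
  race <- race[RACE_LEVELS]
  assert_probability(race, "covariate_distributions$race")
  if (abs(sum(race) - 1) > 1e-9) {
    stop_field("covariate_distributions$race", "probabilities must sum to 1")
  }
  cd$race <- race

  if (!missingness$mechanism %in% c("MCAR", "outcome_dependent")) {
    stop_field("missingness$mechanism", "must be 'MCAR' or 'outcome_dependent'")
  }
  assert_probability(missingness$rate, "missingness$rate")
  if (missingness$mechanism == "outcome_dependent") {
    missingness$logit_shift <- missingness$logit_shift %||% 0
    if (!is.finite(missingness$logit_shift)) {
      stop_field("missingness$logit_shift", "must be finite")
    }
  }

  er_names <- c("prison_transfer", "incarcerated_at_followup", "deceased")
  if (!all(er_names %in% names(exclusion_rates))) {
    stop_field("exclusion_rates",
               paste("must name", paste(er_names, collapse = ", ")))
  }
  exclusion_rates <- exclusion_rates[er_names]
  assert_probability(exclusion_rates, "exclusion_rates")
  if (sum(exclusion_rates) > 1) {
    stop_field("exclusion_rates", "rates must sum to at most 1")
  }

  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed)) {
    stop_field("seed", "must be a single integer")
  }

  structure(
    list(designs = designs, study_intercepts = study_intercepts,
         theta_med = theta_med, theta_pn = theta_pn,
         covariate_effects = covariate_effects,
         covariate_distributions = cd, missingness = missingness,
         exclusion_rates = exclusion_rates, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_covariate_effects <- function() {
  c(age = -0.015, female = -0.25, race_White = 0.15, race_Other = -0.20,
    unhoused = 0.30, stimulant_use = 0.40)
}

#' @rdname sim_config
#' @export
default_covariate_distributions <- function() {
  list(
    age = list(mean = 39.2, sd = 10.9, min = 18, max = 80),
    female = 0.212,
    race = c(Black = 0.491, White = 0.409, Other = 0.100),
    hispanic = 0.294,
    unhoused = 0.319,
    stimulant_use = 0.70
  )
}

# Truncated-normal draws by rejection; the truncation range [18, 80] holds
# essentially all of the N(39.2, 10.9) mass, so rejection is cheap.
rtnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Generate a multi-site randomized cohort
#'
#' Draws one participant record per randomized slot in every design: arm
#' labels with the configured arm sizes, baseline covariates i.i.d. from the
#' configured distributions, and a fully observed binary outcome from the
#' logistic model
#' \deqn{logit P(Y=1) = \alpha_j + \theta^{med}_j [arm \ne ETAU] +
#'       \theta^{pn}_j [arm = MED\_PN] + x'\beta.}
#' Follow-up status is left unset; [apply_followup_process()] adds the
#' missingness and exclusion processes.
#'
#' @param config A [sim_config()] object.
#' @return A participant-record data frame (see [cohort_columns()]), one row
#'   per randomized participant, deterministic given `config$seed`.
#' @examples
#' nrow(generate_cohort(sim_config(seed = 7)))  # 330 for the default registry
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_field("config", "must be created by sim_config()")
  }
  cd <- config$covariate_distributions
  eff <- config$covariate_effects
  out <- vector("list", length(config$designs))
  for (j in seq_along(config$designs)) {
    d <- config$designs[[j]]
    set.seed(substream_seed(config$seed, j))
    n <- sum(d$arm_sizes)
    arm <- rep(names(d$arm_sizes), d$arm_sizes)
    age <- rtnorm(n, cd$age$mean, cd$age$sd, cd$age$min, cd$age$max)
    sex <- ifelse(stats::runif(n) < cd$female, "female", "male")
    race <- sample(RACE_LEVELS, n, replace = TRUE, prob = cd$race)
    hispanic <- stats::runif(n) < cd$hispanic
    unhoused <- stats::runif(n) < cd$unhoused
    stimulant <- stats::runif(n) < cd$stimulant_use
    eta <- config$study_intercepts[j] +
      config$theta_med[j] * (arm != "ETAU") +
      ifelse(arm == "MED_PN", config$theta_pn[j], 0) +
      eff["age"] * (age - cd$age$mean) +
      eff["female"] * (sex == "female") +
      eff["race_White"] * (race == "White") +
      eff["race_Other"] * (race == "Other") +
      eff["unhoused"] * unhoused +
      eff["stimulant_use"] * stimulant
    y <- stats::runif(n) < stats::plogis(eta)
    out[[j]] <- data.frame(
      participant_id = sprintf("%s_%04d", d$study_id, seq_len(n)),
      study_id = d$study_id,
      arm = arm,
      medication_type = ifelse(arm == "ETAU", "none", d$medication_type),
      age = age,
      sex = sex,
      race = race,
      hispanic = hispanic,
      unhoused = unhoused,
      stimulant_use = stimulant,
      follow_up_status = NA_character_,
      outcome = ifelse(y, "positive", "negative"),
      imputed = FALSE,
      stringsAsFactors = FALSE
    )
  }
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  rec
}

#' Apply the follow-up process: exclusions and outcome missingness
#'
#' Assigns each participant a follow-up status (`in_community`,
#' `prison_transfer`, `incarcerated_at_followup`, `deceased`) at the
#' configured rates, then sets the outcome to `missing` among in-community
#' participants according to the configured missingness mechanism.  Under
#' `MCAR` every in-community outcome is masked with the same probability;
#' under `outcome_dependent` the masking probability is shifted on the logit
#' scale by `logit_shift` when the latent outcome is positive.
#'
#' @param records Cohort from [generate_cohort()] (outcomes observed,
#'   follow-up status unset).
#' @param config The [sim_config()] used to generate them.
#' @return The records with `follow_up_status` filled in and some outcomes set
#'   to `"missing"`; deterministic given `config$seed`.
#' @export
apply_followup_process <- function(records, config) {
  if (!inherits(config, "sim_config")) {
    stop_field("config", "must be created by sim_config()")
  }
  validate_records(records, require_status = FALSE)
  if (!all(is.na(records$follow_up_status))) {
    stop_field("records", "follow-up statuses already set")
  }
  if (any(records$outcome == "missing")) {
    stop_field("records", "outcomes must be fully observed before follow-up")
  }
  er <- config$exclusion_rates
  set.seed(substream_seed(config$seed, 101L))
  n <- nrow(records)
  u <- stats::runif(n)
  cuts <- cumsum(c(er["prison_transfer"], er["incarcerated_at_followup"],
                   er["deceased"]))
  status <- rep("in_community", n)
  status[u < cuts[3]] <- "deceased"
  status[u < cuts[2]] <- "incarcerated_at_followup"
  status[u < cuts[1]] <- "prison_transfer"
  records$follow_up_status <- status

  ms <- config$missingness
  in_comm <- which(status == "in_community")
  if (length(in_comm) && ms$rate > 0) {
    if (ms$mechanism == "MCAR") {
      p_miss <- rep(ms$rate, length(in_comm))
    } else {
      pos <- records$outcome[in_comm] == "positive"
      p_miss <- stats::plogis(stats::qlogis(ms$rate) + ms$logit_shift * pos)
    }
    miss <- stats::runif(length(in_comm)) < p_miss
    records$outcome[in_comm[miss]] <- "missing"
  }
  records
}

#' Generate a cohort and run it through the follow-up process
#'
#' Convenience wrapper: [generate_cohort()] then [apply_followup_process()].
#'
#' @inheritParams apply_followup_process
#' @return Participant records ready for [apply_exclusions()] and
#'   [impute_missing_as_positive()].
#' @export
simulate_cohort <- function(config) {
  apply_followup_process(generate_cohort(config), config)
}

#' Design-implied true treatment log-odds ratios
#'
#' Returns the per-study conditional treatment log-ORs configured in the
#' generator and their weighted average, the simulation-side counterpart of
#' the pooled estimand.  Default weights are the per-study total sample
#' sizes.
#'
#' @param config A [sim_config()] object.
#' @param weights Positive per-study weights (default: study sample sizes).
#' @return A list of class `true_parameters` with `theta_j_true` (named) and
#'   `theta_p_true`.
#' @examples
#' true_pooled_log_or(sim_config())$theta_p_true  # log(0.67)
#' @export
true_pooled_log_or <- function(config, weights = NULL) {
  if (!inherits(config, "sim_config")) {
    stop_field("config", "must be created by sim_config()")
  }
  theta <- config$theta_med
  names(theta) <- vapply(config$designs, `[[`, character(1), "study_id")
  if (is.null(weights)) {
    weights <- vapply(config$designs, function(d) sum(d$arm_sizes), numeric(1))
  }
  if (length(weights) != length(theta) || !is.numeric(weights) ||
      any(!is.finite(weights)) || any(weights <= 0)) {
    stop_field("weights", "need one positive weight per study")
  }
  structure(
    list(theta_j_true = theta,
         theta_p_true = sum(weights * theta) / sum(weights)),
    class = "true_parameters"
  )
}
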