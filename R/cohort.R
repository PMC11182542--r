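#' Participant-record columns
#'
#' The cohort data model is a plain data frame with one row per randomized
#' participant and the following columns (types in parentheses):
#' `participant_id` (character, unique), `study_id` (character), `arm`
#' (`ETAU` / `MED` / `MED_PN`), `medication_type` (`XR-NTX` / `IM` / `none`;
#' `none` iff `arm == "ETAU"`), `age` (years), `sex` (`female` / `male`),
#' `race` (`Black` / `White` / `Other`), `hispanic`, `unhoused`,
#' `stimulant_use` (logical; any cocaine/amphetamine use prior to
#' enrollment), `follow_up_status` (`in_community` / `prison_transfer` /
#' `incarcerated_at_followup` / `deceased`, or `NA` before follow-up),
#' `outcome` (`positive` / `negative` / `missing`), `imputed` (logical).
#'
#' @return Character vector of column names in canonical order.
#' @export
cohort_columns <- function() {
  c("participant_id", "study_id", "arm", "medication_type", "age", "sex",
    "race", "hispanic", "unhoused", "stimulant_use", "follow_up_status",
    "outcome", "imputed")
}

validate_records <- function(records, require_status = TRUE) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop_field("records", "must be a nonempty data frame of participant records")
  }
  missing_cols <- setdiff(cohort_columns(), names(records))
  if (length(missing_cols)) {
    stop_field("records", paste("missing column(s):",
                                paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(records$participant_id)) {
    stop_field("participant_id", "must be unique")
  }
  check_levels <- function(x, levels, col, allow_na = FALSE) {
    bad <- if (allow_na) !(x %in% levels | is.na(x)) else !(x %in% levels)
    if (any(bad)) {
      stop_field(col, sprintf("invalid value '%s' (row %d)",
                              x[which(bad)[1]], which(bad)[1]))
    }
  }
  check_levels(records$arm, ARM_LEVELS, "arm")
  check_levels(records$medication_type, MEDICATION_LEVELS, "medication_type")
  check_levels(records$sex, SEX_LEVELS, "sex")
  check_levels(records$race, RACE_LEVELS, "race")
  check_levels(records$outcome, OUTCOME_LEVELS, "outcome")
  if (require_status && anyNA(records$follow_up_status)) {
    i <- which(is.na(records$follow_up_status))[1]
    stop_field("follow_up_status",
               sprintf("unset for participant '%s'", records$participant_id[i]))
  }
  check_levels(records$follow_up_status, STATUS_LEVELS, "follow_up_status",
               allow_na = TRUE)
  bad_med <- (records$arm == "ETAU" & records$medication_type != "none") |
    (records$arm != "ETAU" & records$medication_type == "none")
  if (any(bad_med)) {
    stop_field("medication_type",
               sprintf("inconsistent with arm for participant '%s' (row %d)",
                       records$participant_id[which(bad_med)[1]],
                       which(bad_med)[1]))
  }
  invisible(records)
}

#' Apply post-randomization exclusions
#'
#' Removes participants whose 6-month outcome could not be ascertained in the
#' community: those transferred to prison, those incarcerated at the time of
#' their follow-up interview, and the deceased.  Mirrors a CONSORT-style
#' accounting: the exclusion report gives per-reason counts by study and the
#' excluded participant ids; input order is preserved among kept records.
#'
#' @param records Participant records with `follow_up_status` set.
#' @return A list with `records` (the analytic records, all `in_community`)
#'   and `report` (class `exclusion_report`: `counts` data frame with one row
#'   per study x reason, `excluded_ids`, `n_input`, `n_kept`).
#' @examples
#' cohort <- simulate_cohort(sim_config(exclusion_rates = c(
#'   prison_transfer = 0.1, incarcerated_at_followup = 0.2, deceased = 0.01)))
#' apply_exclusions(cohort)$report$counts
#' @export
apply_exclusions <- function(records) {
  validate_records(records, require_status = TRUE)
  keep <- records$follow_up_status == "in_community"
  excluded <- records[!keep, , drop = FALSE]
  reason_map <- c(prison_transfer = "PRISON_TRANSFER",
                  incarcerated_at_followup = "INCARCERATED",
                  deceased = "DECEASED")
  counts <- data.frame()
  if (nrow(excluded)) {
    tab <- table(study_id = excluded$study_id,
                 reason = reason_map[excluded$follow_up_status])
    counts <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(counts) <- c("study_id", "reason", "n")
    counts <- counts[counts$n > 0, , drop = FALSE]
    rownames(counts) <- NULL
  }
  report <- structure(
    list(counts = counts,
         excluded_ids = excluded$participant_id,
         n_input = nrow(records),
         n_kept = sum(keep)),
    class = "exclusion_report"
  )
  list(records = records[keep, , drop = FALSE], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Exclusions: %d of %d removed, %d analyzed\n",
              x$n_input - x$n_kept, x$n_input, x$n_kept))
  if (nrow(x$counts)) print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Worst-case imputation of missing outcomes
#'
#' Missing 6-month assessments of participants who are alive and in the
#' community are treated as positive (still meeting diagnostic criteria) — the
#' conservative, worst-case-for-treatment convention.  Affected records get
#' `imputed = TRUE`; observed outcomes are untouched.  Must run after
#' [apply_exclusions()]: a record with any other follow-up status is a
#' contract violation.
#'
#' @param records Analytic records (all `in_community`).
#' @return The records with every `missing` outcome replaced by `positive`.
#' @export
impute_missing_as_positive <- function(records) {
  validate_records(records, require_status = TRUE)
  if (any(records$follow_up_status != "in_community")) {
    i <- which(records$follow_up_status != "in_community")[1]
    stop(sprintf(
      "contract violation: participant '%s' has status '%s'; run apply_exclusions() first",
      records$participant_id[i], records$follow_up_status[i]), call. = FALSE)
  }
  miss <- records$outcome == "missing"
  records$outcome[miss] <- "positive"
  records$imputed <- records$imputed | miss
  records
}

round_half_even <- function(x, digits) round(x, digits)

#' Baseline characteristics table
#'
#' Summarizes baseline covariates per group — control (`ETAU`), any
#' treatment (both medication arms collapsed), and overall — with counts and
#' percentages (one decimal) for categorical variables and mean (SD) for
#' continuous ones, the usual trial Table-2 layout.
#'
#' @param records Participant records (any follow-up stage).
#' @param grouping `"treatment"` (default; ETAU vs any treatment vs overall)
#'   or `"study"` (one group per study plus overall).
#' @return Object of class `baseline_summary`: a list with `groups` (named
#'   list of group summaries: `n`, `categorical` data frame with `variable`,
#'   `level`, `count`, `percent`, and `continuous` data frame with
#'   `variable`, `mean`, `sd`) and `grouping`.
#' @examples
#' summarize_baseline(generate_cohort(sim_config(seed = 3)))
#' @export
summarize_baseline <- function(records, grouping = c("treatment", "study")) {
  grouping <- match.arg(grouping)
  validate_records(records, require_status = FALSE)
  if (grouping == "treatment") {
    groups <- list(
      ETAU = records[records$arm == "ETAU", , drop = FALSE],
      any_treatment = records[records$arm != "ETAU", , drop = FALSE]
    )
  } else {
    groups <- split(records, records$study_id)
  }
  groups <- c(groups, list(overall = records))
  groups <- groups[vapply(groups, nrow, integer(1)) > 0]

  cat_vars <- list(
    assignment = function(d) ifelse(d$arm == "ETAU", "ETAU",
                                    ifelse(d$arm == "MED", d$medication_type,
                                           paste0(d$medication_type, "+PN"))),
    sex = function(d) d$sex,
    race = function(d) d$race,
    hispanic = function(d) ifelse(d$hispanic, "yes", "no"),
    unhoused = function(d) ifelse(d$unhoused, "yes", "no"),
    stimulant_use = function(d) ifelse(d$stimulant_use, "yes", "no")
  )

  out <- lapply(groups, function(d) {
    n <- nrow(d)
    cat_rows <- do.call(rbind, lapply(names(cat_vars), function(v) {
      x <- cat_vars[[v]](d)
      tab <- table(x[!is.na(x)])
      data.frame(variable = v, level = names(tab), count = as.integer(tab),
                 percent = round_half_even(100 * as.integer(tab) /
                                             sum(tab), 1),
                 stringsAsFactors = FALSE)
    }))
    sd_age <- if (n > 1) stats::sd(d$age) else {
      warning(sprintf("degenerate group of size 1: SD reported as 0.0"),
              call. = FALSE)
      0
    }
    cont_rows <- data.frame(variable = "age",
                            mean = round_half_even(mean(d$age), 1),
                            sd = round_half_even(sd_age, 1),
                            stringsAsFactors = FALSE)
    list(n = n, categorical = cat_rows, continuous = cont_rows)
  })
  structure(list(groups = out, grouping = grouping),
            class = "baseline_summary")
}

#' @export
print.baseline_summary <- function(x, ...) {
  for (g in names(x$groups)) {
    gr <- x$groups[[g]]
    cat(sprintf("== %s (N = %d) ==\n", g, gr$n))
    for (i in seq_len(nrow(gr$continuous))) {
      cat(sprintf("  %s: mean %.1f (SD %.1f)\n", gr$continuous$variable[i],
                  gr$continuous$mean[i], gr$continuous$sd[i]))
    }
    cc <- gr$categorical
    for (i in seq_len(nrow(cc))) {
      cat(sprintf("  %s = %s: %d (%.1f%%)\n", cc$variable[i], cc$level[i],
                  cc$count[i], cc$percent[i]))
    }
  }
  invisible(x)
}

#' Flatten a baseline summary to one table
#'
#' One row per variable/level/group combination, suitable for writing as a
#' CSV mirroring the usual baseline-table layout.
#'
#' @param x A `baseline_summary`.
#' @param ... Unused.
#' @return A data frame with columns `group`, `variable`, `level`,
#'   `count`, `percent`, `mean`, `sd` (the latter pair filled only for
#'   continuous rows).
#' @export
as.data.frame.baseline_summary <- function(x, ...) {
  do.call(rbind, lapply(names(x$groups), function(g) {
    gr <- x$groups[[g]]
    cats <- cbind(data.frame(group = g, stringsAsFactors = FALSE),
                  gr$categorical, mean = NA_real_, sd = NA_real_)
    cont <- data.frame(group = g, variable = gr$continuous$variable,
                       level = NA_character_, count = NA_integer_,
                       percent = NA_real_, mean = gr$continuous$mean,
                       sd = gr$continuous$sd, stringsAsFactors = FALSE)
    rbind(cats, cont)
  }))
}

#' Read / write participant cohorts as CSV
#'
#' Lossless plain-text round trip of the participant data model (see
#' [cohort_columns()] for the documented header).  Logical flags are stored
#' as `TRUE`/`FALSE`; an unset follow-up status is an empty field.
#'
#' @param path File path.
#' @param records Participant records to write.
#' @param strict If `TRUE` (default) an unrecognized column is an error; if
#'   `FALSE` it is dropped with a warning.
#' @return `read_cohort_csv()` returns a validated record data frame;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop_field("path", paste("no such file:", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  extra <- setdiff(names(raw), cohort_columns())
  if (length(extra)) {
    if (strict) {
      stop_field("columns", paste("unknown column(s):",
                                  paste(extra, collapse = ", ")))
    }
    warning(sprintf("ignoring unrecognized column(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
    raw <- raw[, setdiff(names(raw), extra), drop = FALSE]
  }
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols)) {
    stop_field("columns", paste("missing required column(s):",
                                paste(missing_cols, collapse = ", ")))
  }
  raw <- raw[, cohort_columns()]
  raw$age <- as.numeric(raw$age)
  for (col in c("hispanic", "unhoused", "stimulant_use", "imputed")) {
    val <- toupper(raw[[col]])
    bad <- !val %in% c("TRUE", "FALSE")
    if (any(bad)) {
      stop_field(col, sprintf("unparseable logical '%s' (row %d)",
                              raw[[col]][which(bad)[1]], which(bad)[1]))
    }
    raw[[col]] <- val == "TRUE"
  }
  raw$follow_up_status[raw$follow_up_status == ""] <- NA_character_
  validate_records(raw, require_status = FALSE)
  raw
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(records, path) {
  validate_records(records, require_status = FALSE)
  out <- records[, cohort_columns()]
  out$follow_up_status[is.na(out$follow_up_status)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
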