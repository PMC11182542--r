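#' Define a single-site randomized trial design
#'
#' A study design records the arm sizes of one randomized trial within a
#' multisite collaborative.  Every study has a medication arm (`MED`) and an
#' enhanced treatment-as-usual control arm (`ETAU`); some studies additionally
#' randomize to medication plus patient navigation (`MED_PN`).
#'
#' @param study_id Character label identifying the study (site).
#' @param n_med Number of participants randomized to medication alone.
#' @param n_etau Number of participants randomized to the control condition.
#' @param n_med_pn Number randomized to medication plus patient navigation;
#'   `0` (default) means the study has no navigation arm.
#' @param medication_type Which medication the study used: extended-release
#'   naltrexone (`"XR-NTX"`) or interim methadone (`"IM"`).
#'
#' @return An object of class `study_design`: a list with fields `study_id`,
#'   `arm_sizes` (named integer vector over arms present), `medication_type`
#'   and `has_pn_arm`.
#'
#' @examples
#' study_design("site1", n_med = 58, n_etau = 52, medication_type = "XR-NTX")
#' @export
study_design <- function(study_id, n_med, n_etau, n_med_pn = 0,
                         medication_type = c("XR-NTX", "IM")) {
  medication_type <- match.arg(medication_type)
  if (!is.character(study_id) || length(study_id) != 1L || is.na(study_id) ||
      !nzchar(study_id)) {
    stop_field("study_id", "must be a nonempty character label")
  }
  sizes <- c(n_med = n_med, n_etau = n_etau, n_med_pn = n_med_pn)
  if (!is.numeric(sizes) || any(is.na(sizes)) || any(sizes != round(sizes)) ||
      any(sizes < 0)) {
    stop_field("arm_sizes", "arm sizes must be nonnegative integers")
  }
  if (n_med < 1 || n_etau < 1) {
    stop_field("arm_sizes", "MED and ETAU arms must each have at least 1 participant")
  }
  arm_sizes <- c(ETAU = as.integer(n_etau), MED = as.integer(n_med))
  has_pn <- n_med_pn > 0
  if (has_pn) arm_sizes <- c(arm_sizes, MED_PN = as.integer(n_med_pn))
  structure(
    list(study_id = study_id, arm_sizes = arm_sizes,
         medication_type = medication_type, has_pn_arm = has_pn),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design '%s' (%s): %s\n", x$study_id, x$medication_type,
              paste(sprintf("%s=%d", names(x$arm_sizes), x$arm_sizes),
                    collapse = ", ")))
  invisible(x)
}

#' Default three-site collaborative design registry
#'
#' The registry of the three jail-based randomized trials the package's
#' worked examples emulate: site 1 compared extended-release naltrexone with
#' control (58 vs 52); site 2 added a naltrexone-plus-navigation arm
#' (29/21/19); site 3 compared interim methadone, methadone plus navigation
#' and control (46/54/51).  Combined N = 330.
#'
#' @return A list of three [study_design()] objects.
#' @examples
#' sum(design_registry()$n_total)
#' @export
default_designs <- function() {
  list(
    study_design("site1", n_med = 58, n_etau = 52, medication_type = "XR-NTX"),
    study_design("site2", n_med = 29, n_etau = 19, n_med_pn = 21,
                 medication_type = "XR-NTX"),
    study_design("site3", n_med = 46, n_etau = 51, n_med_pn = 54,
                 medication_type = "IM")
  )
}

#' Tabulate a list of study designs
#'
#' @param designs List of [study_design()] objects (default: the three-site
#'   registry from [default_designs()]).
#'
#' @return A data frame with one row per study (`study_id`,
#'   `medication_type`, `n_med`, `n_med_pn`, `n_etau`, `n_total`).  Column
#'   sums give the collaborative arm totals.
#' @export
design_registry <- function(designs = default_designs()) {
  designs <- validate_designs(designs)
  out <- do.call(rbind, lapply(designs, function(d) {
    data.frame(
      study_id = d$study_id,
      medication_type = d$medication_type,
      n_med = unname(d$arm_sizes["MED"]),
      n_med_pn = if (d$has_pn_arm) unname(d$arm_sizes["MED_PN"]) else 0L,
      n_etau = unname(d$arm_sizes["ETAU"]),
      stringsAsFactors = FALSE
    )
  }))
  out$n_total <- out$n_med + out$n_med_pn + out$n_etau
  out
}

validate_designs <- function(designs) {
  if (!is.list(designs) || length(designs) == 0L) {
    stop_field("designs", "must be a nonempty list of study_design objects")
  }
  # Coerce plain lists (e.g. parsed from a YAML/JSON config) to designs.
  designs <- lapply(designs, function(d) {
    if (inherits(d, "study_design")) return(d)
    if (is.list(d) && !is.null(d$study_id)) {
      return(study_design(d$study_id, n_med = d$n_med, n_etau = d$n_etau,
                          n_med_pn = d$n_med_pn %||% 0,
                          medication_type = d$medication_type %||% "XR-NTX"))
    }
    d
  })
  ok <- vapply(designs, inherits, logical(1), "study_design")
  if (!all(ok)) {
    stop_field("designs", "every element must be created by study_design()")
  }
  ids <- vapply(designs, `[[`, character(1), "study_id")
  if (anyDuplicated(ids)) stop_field("designs", "duplicated study_id")
  designs
}
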