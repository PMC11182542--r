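# Internal helpers shared across modules.

ARM_LEVELS <- c("ETAU", "MED", "MED_PN")
MEDICATION_LEVELS <- c("XR-NTX", "IM", "none")
SEX_LEVELS <- c("female", "male")
RACE_LEVELS <- c("Black", "White", "Other")
STATUS_LEVELS <- c("in_community", "prison_transfer", "incarcerated_at_followup",
                   "deceased")
OUTCOME_LEVELS <- c("positive", "negative", "missing")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# Derive a reproducible substream seed from a root seed; keeps results
# invariant to how many earlier substreams were consumed.  Stays within the
# 32-bit integer range.
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 1000003) %% 2147483647)
}

# Numerically safe log(1 + exp(x)).
log1pexp <- function(x) {
  out <- x
  lo <- x <= 30
  out[lo] <- log1p(exp(x[lo]))
  out
}

bernoulli_loglik <- function(eta, y) {
  sum(y * eta - log1pexp(eta))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

assert_probability <- function(p, field) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_field(field, "must be a probability in [0, 1]")
  }
  invisible(p)
}
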