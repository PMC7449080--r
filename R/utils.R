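# Internal helpers shared across modules.

#' Logit and inverse-logit
#'
#' Numerically safe logit transform and its inverse. `invlogit()` is the
#' standard expit; `logit()` errors on values outside (0, 1).
#'
#' @param p probabilities in (0, 1).
#' @param x real numbers.
#' @return `logit()` returns log(p / (1 - p)); `invlogit()` returns
#'   1 / (1 + exp(-x)).
#' @export
logit <- function(p) {
  if (any(!is.na(p) & (p <= 0 | p >= 1))) {
    stop("logit() requires probabilities strictly inside (0, 1)", call. = FALSE)
  }
  log(p / (1 - p))
}

#' @rdname logit
#' @export
invlogit <- function(x) {
  # stable for large |x|
  ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Configuration error naming the offending field (contract: errors in the
# generator and pipeline name the field that failed validation).
config_error <- function(field, msg) {
  stop(structure(
    class = c("qoc_config_error", "error", "condition"),
    list(message = sprintf("invalid configuration field '%s': %s", field, msg),
         call = NULL, field = field)
  ))
}

check_prob <- function(x, field, open = TRUE) {
  bad <- if (open) any(x <= 0 | x >= 1) else any(x < 0 | x > 1)
  if (any(is.na(x)) || bad) {
    config_error(field, if (open) "must lie strictly inside (0, 1)"
                 else "must lie in [0, 1]")
  }
  invisible(x)
}

# Days between two Date (or coercible) vectors, as integer.
days_between <- function(from, to) as.integer(as.Date(to) - as.Date(from))

# Deterministic seed derivation: keeps derived seeds inside 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1103L * offset) %% .Machine$integer.max)
}

# Short content hash used in run manifests (md5 of a canonical JSON dump).
hash_object <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

indicator_names <- function() {
  c("test_and_start", "viral_load", "mms_appropriate",
    "timely_pickup", "retention_adult", "retention_pregnant")
}

indicator_labels <- function() {
  c("Test and start (ART within 1 month of diagnosis)",
    "Viral load testing up to date",
    "Appropriate multi-month scripting (MMS)",
    "Timely ART pick-up",
    "6-month ART retention, non-pregnant adults",
    "6-month ART retention, pregnant/post-partum women")
}
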