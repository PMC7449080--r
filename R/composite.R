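# Composite performance measure: per-indicator z-scores on a common
# failure scale, capping at +/-3, relevance weighting, adjustment for
# inter-indicator correlation, and final standardization to mean 0 / sd 1
# across facilities.

#' Default relevance weights for the six indicators
#'
#' Three-point relevance/reliability scale (low 0.5, medium 1, high 1.5):
#' the three process-of-care indicators carry 1.5, timely pick-up and
#' adult retention 0.5, and retention of pregnant women 1.
#' @return named length-6 numeric vector.
#' @export
default_weights <- function() {
  stats::setNames(c(1.5, 1.5, 1.5, 0.5, 0.5, 1), indicator_names())
}

#' Facility x indicator z-score matrix
#'
#' Indicators 1-3: `z = (p_i - pi0) / (sqrt(phi) sqrt(pi0 (1 - pi0) / n))`;
#' indicators 4-6: `z = y_i / (s_i sqrt(phi))` (or the additive analogue if
#' the profile was run that way). Positive z always means more failure.
#' Facilities with an empty denominator get a missing entry.
#'
#' @param profile a `qoc_profile` from [profile_facilities()].
#' @return numeric matrix, rows = facilities, columns = the six indicators.
#' @export
indicator_zscores <- function(profile) {
  pr <- data.table::as.data.table(profile)
  wide <- data.table::dcast(pr, facility_id ~ indicator, value.var = "z")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$facility_id
  full <- matrix(NA_real_, nrow(m), 6,
                 dimnames = list(rownames(m), indicator_names()))
  full[, as.integer(colnames(m))] <- m
  full
}

#' Cap z-scores
#'
#' @param z numeric vector/matrix.
#' @param bound cap (default 3): values are clamped to `[-bound, bound]`
#'   so a single indicator cannot dominate the composite.
#' @return capped values, same shape.
#' @export
cap_zscores <- function(z, bound = 3) {
  stopifnot(bound > 0)
  # z first so pmin/pmax keep its dim attributes
  pmin(pmax(z, -bound), bound)
}

# Repair a correlation matrix that pairwise-complete estimation left
# non-positive-semi-definite: clip negative eigenvalues at 0 and rescale
# the diagonal back to 1.
repair_correlation <- function(R) {
  R[is.na(R)] <- 0
  diag(R) <- 1
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (all(e$values >= -1e-10)) return((R + t(R)) / 2)
  v <- pmax(e$values, 0)
  R2 <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(R2))
  d[d == 0] <- 1
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  R2
}

#' Composite performance z-score
#'
#' Caps the facility x indicator z-scores, estimates the inter-indicator
#' correlation matrix `R` of the capped scores (pairwise-complete,
#' eigenvalue-repaired if needed), forms the relevance-weighted mean
#' normalized by the standard deviation of the weighted sum,
#' `sum_k w_k z_ik / sqrt(w' R w)` (restricted to the facility's available
#' indicators), and finally standardizes across included facilities so the
#' composite behaves as a regular z-score: mean 0, sd 1. Facilities with
#' more than `6 - min_indicators` missing indicators are excluded.
#'
#' @param zmat matrix from [indicator_zscores()].
#' @param weights relevance weights (default [default_weights()]).
#' @param cap z-score cap (default 3).
#' @param threshold classification threshold on the composite (default 2:
#'   `Z > 2` low performer, `Z < -2` high performer, strict inequalities).
#' @param min_indicators minimum available indicators (default 4).
#' @param R optional fixed inter-indicator correlation matrix (6 x 6);
#'   when NULL (default) it is estimated from the capped z-scores.
#' @return `data.table` of class `qoc_composite`: capped z columns,
#'   `n_available`, `composite_raw`, `composite`, `class`, `included`;
#'   attributes `R` (correlation used) and `weights`.
#' @export
composite_scores <- function(zmat, weights = default_weights(), cap = 3,
                             threshold = 2, min_indicators = 4, R = NULL) {
  stopifnot(is.matrix(zmat), ncol(zmat) == 6)
  weights <- rep_len(unname(weights), 6)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  zc <- cap_zscores(zmat, cap)
  if (is.null(R)) {
    R <- suppressWarnings(stats::cor(zc, use = "pairwise.complete.obs"))
  }
  R <- repair_correlation(R)

  n_avail <- rowSums(!is.na(zc))
  raw <- rep(NA_real_, nrow(zc))
  for (i in seq_len(nrow(zc))) {
    a <- which(!is.na(zc[i, ]))
    if (length(a) < min_indicators) next
    wa <- weights[a]
    denom <- sqrt(drop(t(wa) %*% R[a, a, drop = FALSE] %*% wa))
    raw[i] <- sum(wa * zc[i, a]) / denom
  }
  included <- !is.na(raw)
  if (any(!included)) {
    message(sprintf(
      "%d facility(ies) excluded from the composite (fewer than %d indicators available)",
      sum(!included), min_indicators))
  }
  if (sum(included) < 2) {
    stop("fewer than two facilities with enough indicators for a composite",
         call. = FALSE)
  }
  mu <- mean(raw[included])
  sd0 <- stats::sd(raw[included])
  if (sd0 == 0) sd0 <- 1
  z <- (raw - mu) / sd0
  out <- data.table::data.table(facility_id = rownames(zmat))
  for (k in 1:6) data.table::set(out, j = paste0("z", k), value = zc[, k])
  out[, `:=`(n_available = n_avail, composite_raw = raw, composite = z,
             included = included)]
  out[, class := data.table::fcase(
    !included, NA_character_,
    composite > threshold, "low_performer",
    composite < -threshold, "high_performer",
    default = "typical")]
  data.table::setattr(out, "R", R)
  data.table::setattr(out, "weights", weights)
  data.table::setattr(out, "threshold", threshold)
  data.table::setattr(out, "class", c("qoc_composite", class(out)))
  out[]
}

#' Classify a standardized composite score
#'
#' @param composite standardized composite z-scores.
#' @param threshold strict threshold (default 2; 1.25 is the permissive
#'   alternative used when a longer inspection list is wanted).
#' @return "low_performer" (Z > threshold), "high_performer"
#'   (Z < -threshold) or "typical".
#' @export
classify_performance <- function(composite, threshold = 2) {
  data.table::fcase(is.na(composite), NA_character_,
                    composite > threshold, "low_performer",
                    composite < -threshold, "high_performer",
                    default = "typical")
}

#' @export
print.qoc_composite <- function(x, ...) {
  inc <- sum(x$included)
  cat(sprintf("<qoc_composite> %d facilities (%d included)\n", nrow(x), inc))
  cat(sprintf("  composite: mean %.2e, sd %.6f\n",
              mean(x$composite[x$included]),
              stats::sd(x$composite[x$included])))
  tb <- table(x$class[x$included])
  cat("  classes:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  invisible(x)
}
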