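# Facility-level hypothesis tests, over-dispersion estimation, and
# Bonferroni-corrected outlier flagging.
#
# Indicators 1-3 are tested against an exact binomial null with mean pi0;
# indicators 4-6 against a standard-normal null for the case-mix-adjusted
# logit contrast y/s. Over-dispersion is handled either multiplicatively
# (standard errors inflated by sqrt(phi), phi from a winsorized z-score
# estimator) or additively (between-facility variance tau2 by method of
# moments). When an inflation is in effect the binomial indicators are
# tested on the normal-approximation z scale, since the exact binomial
# tail has no sqrt(phi) analogue.

#' Exact binomial tail p-value against a target proportion
#'
#' Tail probabilities include the observed point; the two-sided p-value is
#' twice the smaller tail, capped at 1.
#'
#' @param x failure counts.
#' @param n denominators (n >= 1; zero-denominator units must be skipped
#'   upstream).
#' @param pi0 null failure proportion in (0, 1).
#' @param side "upper", "lower" or "two_sided".
#' @return p-values (vectorized).
#' @export
binom_pvalue <- function(x, n, pi0, side = c("two_sided", "upper", "lower")) {
  side <- match.arg(side)
  stopifnot(all(n >= 1), all(x >= 0 & x <= n), all(pi0 > 0 & pi0 < 1))
  up <- stats::pbinom(x - 1, n, pi0, lower.tail = FALSE)  # P(X >= x)
  lo <- stats::pbinom(x, n, pi0)                          # P(X <= x)
  switch(side,
         upper = up,
         lower = lo,
         two_sided = pmin(1, 2 * pmin(up, lo)))
}

#' Normal p-value and z-score for an adjusted contrast
#'
#' `z = y / (s * sqrt(phi))` under the multiplicative over-dispersion model
#' or `z = y / sqrt(s^2 + tau2)` under the additive random-effects model;
#' the p-value is two-sided standard normal.
#'
#' @param y logit-scale contrasts.
#' @param s their standard errors (> 0).
#' @param phi multiplicative over-dispersion factor (>= 1).
#' @param tau2 additive between-facility variance; when non-NULL the
#'   additive model is used and `phi` is ignored.
#' @return `data.table` with `z` and `p_value`.
#' @export
normal_pvalue <- function(y, s, phi = 1, tau2 = NULL) {
  stopifnot(all(s > 0))
  z <- if (!is.null(tau2)) y / sqrt(s^2 + tau2) else y / (s * sqrt(phi))
  data.table::data.table(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

# Null expectation of the winsorized squared z-score under N(0,1): used to
# debias the winsorized over-dispersion estimator so that E[phi_hat] = 1
# under the null for any winsorizing fraction.
winsor_null_factor <- function(w) {
  if (w <= 0) return(1)
  q <- stats::qnorm(1 - w)
  (1 - 2 * w) - 2 * q * stats::dnorm(q) + 2 * w * q^2
}

#' Winsorized over-dispersion factor phi
#'
#' Winsorizes the unadjusted facility z-scores at the `w` and `1 - w`
#' empirical quantiles, averages their squares, and rescales by the null
#' expectation of a winsorized squared standard normal so the estimator is
#' unbiased (equal to 1 in expectation) when no over-dispersion is
#' present. The reported `phi` is floored at 1 (standard errors are never
#' deflated). An inflation is recommended only when the raw estimate
#' exceeds `1 + 2 * sqrt(2 / I)`, i.e. roughly two standard errors of a
#' chi-square mean under the null.
#'
#' @param z unadjusted z-scores, one per facility.
#' @param winsor winsorizing fraction (default 0.1).
#' @return list with `phi` (floored), `phi_raw` (debiased, unfloored),
#'   `inflate` (logical recommendation) and `I`.
#' @export
estimate_phi <- function(z, winsor = 0.1) {
  z <- z[is.finite(z)]
  I <- length(z)
  stopifnot(I >= 2, winsor >= 0, winsor < 0.5)
  qs <- stats::quantile(z, c(winsor, 1 - winsor), names = FALSE, type = 7)
  zw <- pmin(pmax(z, qs[1]), qs[2])
  phi_raw <- mean(zw^2) / winsor_null_factor(winsor)
  list(phi = max(1, phi_raw), phi_raw = phi_raw,
       inflate = phi_raw > 1 + 2 * sqrt(2 / I), I = I)
}

#' Method-of-moments between-facility variance tau2
#'
#' Random-effects (additive) over-dispersion model: each facility's true
#' level is normal around the national mean with variance `tau2`. The
#' estimator is the usual precision-weighted method of moments
#' (DerSimonian-Laird form) on the standardized contrasts, floored at 0.
#'
#' @param y contrasts; `s` their standard errors.
#' @param s standard errors (> 0).
#' @return tau2 estimate (>= 0).
#' @export
estimate_tau2 <- function(y, s) {
  keep <- is.finite(y) & is.finite(s) & s > 0
  y <- y[keep]; s <- s[keep]
  I <- length(y)
  stopifnot(I >= 2)
  w <- 1 / s^2
  yb <- sum(w * y) / sum(w)
  q <- sum(w * (y - yb)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  max(0, (q - (I - 1)) / denom)
}

#' Bonferroni-corrected outlier flags
#'
#' A facility is flagged when its p-value falls strictly below
#' `alpha / I`, with direction taken from the sign of its deviation
#' (positive = more failure = low performer).
#'
#' @param p_value p-values.
#' @param direction numeric deviations (e.g. `p - pi0` or `y`).
#' @param alpha nominal familywise level (default 0.05).
#' @param I number of facilities tested on the indicator.
#' @return character flags: "none", "low_performer" or "high_performer".
#' @export
flag_outliers <- function(p_value, direction, alpha = 0.05,
                          I = length(p_value)) {
  thr <- alpha / I
  data.table::fcase(
    p_value < thr & direction > 0, "low_performer",
    p_value < thr & direction < 0, "high_performer",
    default = "none")
}

#' Profile all facilities on all six indicators
#'
#' Runs the per-facility hypothesis tests with the chosen over-dispersion
#' treatment and flags outliers at the Bonferroni-corrected threshold.
#'
#' With `method = "none"`, indicators 1-3 use exact binomial tail p-values
#' and 4-6 the plain normal approximation. With `method = "multiplicative"`
#' every indicator is tested on the z scale with standard errors inflated
#' by `sqrt(phi)` (phi estimated per indicator and floored at 1; if the
#' estimate does not clear the decision rule in [estimate_phi()] no
#' inflation is applied). With `method = "additive"` the between-facility
#' variance `tau2` is added to each squared standard error instead.
#'
#' @param aggregates `qoc_aggregates` (indicators 1-3 and denominators).
#' @param contrasts contrasts table from [casemix_contrasts()] (4-6).
#' @param alpha nominal familywise level.
#' @param method "multiplicative", "additive" or "none".
#' @param winsor winsorizing fraction for phi.
#' @param force_inflation ignore the inflation decision rule and always
#'   apply the estimated phi (used for matched funnel/test comparisons).
#' @return `data.table` of class `qoc_profile`: one row per facility x
#'   indicator with `z`, `p_value`, `phi`, `tau2`, `flag`, `alpha`, `I`,
#'   `method`.
#' @export
profile_facilities <- function(aggregates, contrasts = NULL, alpha = 0.05,
                               method = c("multiplicative", "additive",
                                          "none"),
                               winsor = 0.1, force_inflation = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(aggregates, "qoc_aggregates"))
  agg <- aggregates$aggregates
  pi0 <- aggregates$pi0
  out <- list()

  for (k in 1:6) {
    if (k <= 3) {
      ak <- agg[indicator == k & denominator > 0]
      if (nrow(ak) == 0) next
      y <- ak$proportion - pi0[k]
      s <- sqrt(pi0[k] * (1 - pi0[k]) / ak$denominator)
      dt <- data.table::data.table(facility_id = ak$facility_id,
                                   indicator = k, observed = ak$proportion,
                                   target = pi0[k], y = y, s = s,
                                   denominator = ak$denominator)
    } else {
      if (is.null(contrasts) || nrow(contrasts) == 0) next
      ck <- contrasts[contrasts$indicator == k, ]
      if (nrow(ck) == 0) next
      dt <- data.table::data.table(facility_id = ck$facility_id,
                                   indicator = k, observed = ck$observed,
                                   target = 0, y = ck$y, s = ck$s,
                                   denominator = ck$n)
    }
    I <- nrow(dt)
    z0 <- dt$y / dt$s
    ph <- estimate_phi(z0, winsor)
    tau2 <- estimate_tau2(dt$y, dt$s)
    use_phi <- if (method == "multiplicative" &&
                   (ph$inflate || force_inflation)) ph$phi else 1
    use_tau2 <- if (method == "additive") tau2 else 0

    if (method == "none" && k <= 3) {
      ak <- agg[indicator == k & denominator > 0]
      p <- binom_pvalue(ak$failures, ak$denominator, pi0[k], "two_sided")
      z <- z0
    } else if (method == "additive") {
      np <- normal_pvalue(dt$y, dt$s, tau2 = use_tau2)
      z <- np$z; p <- np$p_value
    } else {
      np <- normal_pvalue(dt$y, dt$s, phi = use_phi)
      z <- np$z; p <- np$p_value
    }
    dt[, `:=`(z_unadjusted = z0, z = z, p_value = p,
              phi = ph$phi, phi_raw = ph$phi_raw,
              phi_applied = use_phi, tau2 = tau2,
              tau2_applied = use_tau2,
              alpha = alpha, I = I, method = method)]
    dt[, flag := flag_outliers(p_value, y, alpha, I)]
    out[[k]] <- dt
  }
  res <- data.table::rbindlist(out)
  res[, indicator_name := indicator_names()[indicator]]
  data.table::setattr(res, "class",
                      c("qoc_profile", class(res)))
  res[]
}

#' @export
print.qoc_profile <- function(x, ...) {
  cat("<qoc_profile>", nrow(x), "facility x indicator tests,",
      "method:", x$method[1], "\n")
  fl <- x[x$flag != "none", ]
  cat(sprintf("  flags: %d low, %d high (alpha/I threshold)\n",
              sum(fl$flag == "low_performer"),
              sum(fl$flag == "high_performer")))
  ph <- unique(data.table::as.data.table(x)[, .(indicator, phi_raw, tau2)])
  cat("  phi_raw:", paste(sprintf("%.2f", ph$phi_raw), collapse = " "),
      "\n")
  invisible(x)
}
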