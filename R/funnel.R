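# Funnel plots: target lines, control-limit curves (plain and
# over-dispersed), facility coordinates, and in/out-of-funnel status.
#
# Limits are normal-approximation throughout, matching the z-score
# construction used for phi estimation and the composite (the sqrt(phi)
# inflation has no exact-binomial analogue); exact binomial tails remain
# available for flagging via profile_facilities(method = "none").

level_to_z <- function(level) stats::qnorm((1 + level) / 2)

#' Binomial funnel control limits (proportion scale)
#'
#' `pi0 +/- z* . sqrt(phi) . sqrt(pi0 (1 - pi0) / n)` (multiplicative), or
#' `pi0 +/- z* . sqrt(pi0 (1 - pi0) / n + tau2)` (additive), truncated to
#' \[0, 1\].
#'
#' @param pi0 target proportion in (0, 1).
#' @param n precision grid (denominators, >= 1).
#' @param level two-sided coverage level(s) in (0, 1).
#' @param phi multiplicative over-dispersion factor.
#' @param tau2 additive between-facility variance (used when > 0).
#' @return `data.table`: `n`, `level`, `lower`, `upper`, `target`.
#' @export
binomial_limits <- function(pi0, n, level = 0.95, phi = 1, tau2 = 0) {
  stopifnot(pi0 > 0, pi0 < 1, all(n >= 1), all(level > 0 & level < 1))
  grid <- data.table::CJ(n = as.numeric(n), level = level)
  se <- sqrt(pi0 * (1 - pi0) / grid$n)
  hw <- if (tau2 > 0) level_to_z(grid$level) * sqrt(se^2 + tau2)
        else level_to_z(grid$level) * sqrt(phi) * se
  grid[, `:=`(lower = pmax(0, pi0 - hw), upper = pmin(1, pi0 + hw),
              target = pi0)]
  grid[]
}

#' Normal funnel control limits for adjusted contrasts
#'
#' Target 0; precision is `rho = 1/s`. Limits are
#' `+/- z* . sqrt(phi) / rho` (multiplicative) or
#' `+/- z* . sqrt(1 / rho^2 + tau2)` (additive; these asymptote to
#' `+/- z* . tau` instead of closing onto the target).
#'
#' @param rho precision grid (1/standard error, > 0).
#' @param level two-sided coverage level(s).
#' @param phi,tau2 over-dispersion parameters as in [binomial_limits()].
#' @return `data.table`: `rho`, `level`, `lower`, `upper`, `target`.
#' @export
normal_limits <- function(rho, level = 0.95, phi = 1, tau2 = 0) {
  stopifnot(all(rho > 0), all(level > 0 & level < 1))
  grid <- data.table::CJ(rho = as.numeric(rho), level = level)
  hw <- if (tau2 > 0) level_to_z(grid$level) * sqrt(1 / grid$rho^2 + tau2)
        else level_to_z(grid$level) * sqrt(phi) / grid$rho
  grid[, `:=`(lower = -hw, upper = hw, target = 0)]
  grid[]
}

#' Funnel curves and facility coordinates for a profiled run
#'
#' Builds, per indicator, the target line and two sets of control limits
#' (plain and over-dispersion-adjusted) at both the conventional 95% level
#' and the Bonferroni-corrected level `1 - alpha / I`, plus each facility's
#' plot coordinates and in/out-of-funnel status per variant.
#'
#' Classification against the over-dispersed Bonferroni limits agrees with
#' the z-based Bonferroni flag by construction.
#'
#' @param profile a `qoc_profile` from [profile_facilities()].
#' @param levels base coverage level(s); the Bonferroni level is added.
#' @param grid_points points per limit curve.
#' @return list of class `qoc_funnel` with `curves` and `points`
#'   `data.table`s.
#' @export
funnel_data <- function(profile, levels = 0.95, grid_points = 200) {
  pr <- data.table::as.data.table(profile)
  curves <- list(); pts <- list()
  for (k in sort(unique(pr$indicator))) {
    pk <- pr[indicator == k]
    I <- pk$I[1]; alpha <- pk$alpha[1]
    lv <- sort(unique(c(levels, 1 - alpha / I)))
    phi_od <- if (pk$method[1] == "additive") 1 else pk$phi_applied[1]
    tau_od <- pk$tau2_applied[1]
    if (k <= 3) {
      ngrid <- unique(round(exp(seq(log(max(1, min(pk$denominator))),
                                    log(max(pk$denominator)),
                                    length.out = grid_points))))
      plain <- binomial_limits(pk$target[1], ngrid, lv)
      od <- binomial_limits(pk$target[1], ngrid, lv, phi = phi_od,
                            tau2 = tau_od)
      plain[, `:=`(indicator = k, variant = "plain")]
      od[, `:=`(indicator = k, variant = "overdispersed")]
      data.table::setnames(plain, "n", "precision")
      data.table::setnames(od, "n", "precision")
      xy <- pk[, .(facility_id, indicator, precision = denominator,
                   value = observed)]
      se <- sqrt(pk$target[1] * (1 - pk$target[1]) / pk$denominator)
    } else {
      rho <- 1 / pk$s
      rgrid <- seq(min(rho) * 0.9, max(rho) * 1.05, length.out = grid_points)
      plain <- normal_limits(rgrid, lv)
      od <- normal_limits(rgrid, lv, phi = phi_od, tau2 = tau_od)
      plain[, `:=`(indicator = k, variant = "plain")]
      od[, `:=`(indicator = k, variant = "overdispersed")]
      data.table::setnames(plain, "rho", "precision")
      data.table::setnames(od, "rho", "precision")
      xy <- pk[, .(facility_id, indicator, precision = 1 / s, value = y)]
      se <- pk$s
    }
    bonf_z <- level_to_z(1 - alpha / I)
    base_z <- level_to_z(max(levels))
    infl <- if (pk$method[1] == "additive") sqrt(pk$s^2 * 0 + 1) else 1
    dev <- pk$y
    sd_plain <- se
    sd_od <- if (pk$method[1] == "additive") sqrt(se^2 + tau_od)
             else se * sqrt(phi_od)
    xy[, `:=`(
      status_plain = data.table::fcase(
        dev > base_z * sd_plain, "low_performer",
        dev < -base_z * sd_plain, "high_performer",
        default = "inside"),
      status_plain_bonf = data.table::fcase(
        dev > bonf_z * sd_plain, "low_performer",
        dev < -bonf_z * sd_plain, "high_performer",
        default = "inside"),
      status_overdispersed = data.table::fcase(
        dev > base_z * sd_od, "low_performer",
        dev < -base_z * sd_od, "high_performer",
        default = "inside"),
      status_overdispersed_bonf = data.table::fcase(
        dev > bonf_z * sd_od, "low_performer",
        dev < -bonf_z * sd_od, "high_performer",
        default = "inside"))]
    curves[[length(curves) + 1L]] <- data.table::rbindlist(list(plain, od),
                                                           use.names = TRUE)
    pts[[length(pts) + 1L]] <- xy
  }
  structure(list(curves = data.table::rbindlist(curves),
                 points = data.table::rbindlist(pts)),
            class = "qoc_funnel")
}

#' Plot one indicator's funnel
#'
#' Base-graphics rendering: facility points, target line, and the plain
#' (solid) and over-dispersed (dashed) Bonferroni-corrected control limits.
#'
#' @param funnel a `qoc_funnel` from [funnel_data()].
#' @param indicator indicator number 1-6.
#' @param main optional title.
#' @return invisibly, the plotted points table.
#' @export
plot_funnel <- function(funnel, indicator, main = NULL) {
  cv <- funnel$curves[funnel$curves$indicator == indicator, ]
  pt <- funnel$points[funnel$points$indicator == indicator, ]
  if (nrow(pt) == 0) stop("no facilities for this indicator")
  bl <- max(cv$level)  # Bonferroni level is the widest
  cvb <- cv[cv$level == bl, ]
  ylim <- range(c(pt$value, cvb$lower, cvb$upper), finite = TRUE)
  graphics::plot(pt$precision, pt$value, pch = 16,
                 col = ifelse(pt$status_overdispersed_bonf == "inside",
                              "grey30", "red3"),
                 xlab = if (indicator <= 3) "denominator (volume)"
                        else "precision (1/s)",
                 ylab = if (indicator <= 3) "observed failure proportion"
                        else "logit contrast y",
                 main = main %||% indicator_labels()[indicator],
                 ylim = ylim, log = if (indicator <= 3) "x" else "")
  graphics::abline(h = cvb$target[1], col = "grey50")
  for (vr in c("plain", "overdispersed")) {
    cc <- cvb[cvb$variant == vr, ]
    cc <- cc[order(cc$precision), ]
    graphics::lines(cc$precision, cc$lower,
                    lty = if (vr == "plain") 1 else 2)
    graphics::lines(cc$precision, cc$upper,
                    lty = if (vr == "plain") 1 else 2)
  }
  invisible(pt)
}
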