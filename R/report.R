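# Human-readable run report (markdown text).

#' Render a markdown report for a profiling run
#'
#' Lists, per indicator, every facility flagged at the Bonferroni-corrected
#' threshold (direction, p-value, and whether it also sits outside each
#' funnel variant), then the composite section: facilities beyond the
#' classification threshold and facilities excluded for insufficient
#' indicators.
#'
#' @param bundle a `qoc_bundle` from [run_pipeline()].
#' @return character vector of markdown lines (one per element).
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "qoc_bundle"))
  pr <- data.table::as.data.table(bundle$profile)
  pts <- bundle$funnel$points
  comp <- bundle$composite
  thr <- attr(comp, "threshold") %||% 2
  lines <- c("# Facility quality-of-care profiling report", "",
             sprintf("- facilities: %d; patients: %d",
                     bundle$manifest$n_facilities,
                     bundle$manifest$n_patients),
             sprintf("- over-dispersion method: %s; alpha = %g (Bonferroni alpha/I)",
                     pr$method[1], pr$alpha[1]), "")

  lines <- c(lines, "## Flagged facilities by indicator", "")
  any_flag <- FALSE
  for (k in 1:6) {
    pk <- pr[indicator == k & flag != "none"]
    lines <- c(lines, sprintf("### %d. %s", k, indicator_labels()[k]))
    if (nrow(pk) == 0) {
      lines <- c(lines, "", "No outliers detected.", "")
      next
    }
    any_flag <- TRUE
    pk <- pk[order(p_value)]
    st <- pts[pts$indicator == k,
              c("facility_id", "status_plain_bonf",
                "status_overdispersed_bonf")]
    pk <- merge(pk, st, by = "facility_id", sort = FALSE)
    lines <- c(lines, "",
               "| facility | direction | p-value | plain funnel | over-dispersed funnel |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s | %.2e | %s | %s |",
                       pk$facility_id, pk$flag, pk$p_value,
                       pk$status_plain_bonf, pk$status_overdispersed_bonf),
               "")
  }
  if (!any_flag) {
    lines <- c(lines, "_No outliers detected on any indicator._", "")
  }

  lines <- c(lines, "## Composite performance", "")
  out <- comp[comp$included & comp$class != "typical", ]
  if (nrow(out) == 0) {
    lines <- c(lines,
               sprintf("No facility beyond the +/-%.2g composite threshold.",
                       thr), "")
  } else {
    out <- out[order(-abs(out$composite)), ]
    lines <- c(lines,
               "| facility | composite Z | class |", "|---|---|---|",
               sprintf("| %s | %.2f | %s |", out$facility_id,
                       out$composite, out$class), "")
  }
  excl <- comp[!comp$included, ]
  if (nrow(excl)) {
    lines <- c(lines, sprintf(
      "Excluded from the composite (insufficient indicators): %s.",
      paste(sprintf("%s (%d of 6 available)", excl$facility_id,
                    excl$n_available), collapse = ", ")), "")
  }
  lines
}
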