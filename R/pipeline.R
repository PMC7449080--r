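# End-to-end pipeline: configuration, stage orchestration, CSV outputs,
# and a reproducible run manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the full profiling run. Defaults equal the
#' published constants of the method: alpha = 0.05, z-cap 3, composite
#' threshold 2, relevance weights (1.5, 1.5, 1.5, 0.5, 0.5, 1), 10%
#' winsorization, multiplicative over-dispersion as primary.
#'
#' @param input_dir directory of EMR CSVs (NULL to simulate).
#' @param sim a [sim_config()] used when `input_dir` is NULL.
#' @param window observation window; defaults to the simulation's (or the
#'   data range on read).
#' @param alpha nominal familywise level.
#' @param overdispersion "multiplicative", "additive" or "none".
#' @param winsor winsorizing fraction for phi.
#' @param adjust apply the case-mix adjustment to indicators 4-6.
#' @param casemix_formula optional model formula override.
#' @param weights,cap,threshold,min_indicators composite parameters.
#' @param grace_days,ttt_window_days,vl_eligibility_lag_days,vl_recency_window_days
#'   indicator parameters.
#' @param out_dir output directory (NULL: nothing written).
#' @param seed integer; seeds the simulation when `input_dir` is NULL.
#' @return a list of class `qoc_pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, sim = NULL, window = NULL,
                            alpha = 0.05,
                            overdispersion = c("multiplicative", "additive",
                                               "none"),
                            winsor = 0.1, adjust = TRUE,
                            casemix_formula = NULL,
                            weights = default_weights(), cap = 3,
                            threshold = 2, min_indicators = 4,
                            grace_days = 30, ttt_window_days = 30,
                            vl_eligibility_lag_days = 180,
                            vl_recency_window_days = 365,
                            out_dir = NULL, seed = 20160601) {
  overdispersion <- match.arg(overdispersion)
  if (alpha <= 0 || alpha >= 1) config_error("alpha", "must be in (0, 1)")
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    config_error("input_dir", "directory does not exist")
  }
  if (is.null(input_dir) && is.null(sim)) sim <- sim_config(seed = seed)
  structure(list(input_dir = input_dir, sim = sim, window = window,
                 alpha = alpha, overdispersion = overdispersion,
                 winsor = winsor, adjust = adjust,
                 casemix_formula = casemix_formula, weights = weights,
                 cap = cap, threshold = threshold,
                 min_indicators = min_indicators, grace_days = grace_days,
                 ttt_window_days = ttt_window_days,
                 vl_eligibility_lag_days = vl_eligibility_lag_days,
                 vl_recency_window_days = vl_recency_window_days,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "qoc_pipeline_config")
}

#' Run the full profiling pipeline
#'
#' Simulates (or reads) the EMR, computes per-unit indicator flags,
#' aggregates to facility counts with the national target `pi0`, fits the
#' case-mix models and adjusted contrasts, runs the facility tests with
#' over-dispersion handling and Bonferroni flagging, builds the funnel
#' curves, and computes the composite score. Stage outputs (and a run
#' manifest with a config hash) are written as CSVs when `out_dir` is set.
#' A rerun with the same config and inputs is bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return a list of class `qoc_bundle`: `emr`, `flags`, `aggregates`,
#'   `contrasts`, `models`, `profile`, `funnel`, `composite`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "qoc_pipeline_config"))
  emr <- if (is.null(config$input_dir)) simulate_emr(config$sim)
         else read_emr(config$input_dir, window = config$window)
  message(sprintf("[qoc] data: %d facilities, %d patients, %d dispense events",
                  nrow(emr$facilities), nrow(emr$patients),
                  nrow(emr$dispenses)))
  params <- indicator_params(
    window = config$window %||% emr$window,
    ttt_window_days = config$ttt_window_days,
    grace_days = config$grace_days,
    vl_eligibility_lag_days = config$vl_eligibility_lag_days,
    vl_recency_window_days = config$vl_recency_window_days)

  flags <- compute_indicators(emr, params)
  agg <- aggregate_indicators(flags, emr$facilities)
  message(sprintf("[qoc] indicators: denominators %s",
                  paste(agg$aggregates[, sum(denominator), by = indicator]$V1,
                        collapse = "/")))
  cm <- casemix_contrasts(flags, emr, agg, adjust = config$adjust,
                          formula = config$casemix_formula)
  message(sprintf("[qoc] case-mix: %d adjusted contrasts (%d models)",
                  nrow(cm$contrasts), length(cm$models)))
  profile <- profile_facilities(agg, cm$contrasts, alpha = config$alpha,
                                method = config$overdispersion,
                                winsor = config$winsor)
  message(sprintf("[qoc] profiling: %d flags at alpha/I (%s over-dispersion)",
                  sum(profile$flag != "none"), config$overdispersion))
  funnel <- funnel_data(profile)
  zmat <- indicator_zscores(profile)
  composite <- composite_scores(zmat, weights = config$weights,
                                cap = config$cap,
                                threshold = config$threshold,
                                min_indicators = config$min_indicators)

  manifest <- list(
    package_version = as.character(utils::packageVersion("qocprofile")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = hash_object(config[setdiff(names(config), "out_dir")]),
    n_facilities = nrow(emr$facilities),
    n_patients = nrow(emr$patients),
    n_dispenses = nrow(emr$dispenses),
    n_labs = nrow(emr$labs),
    rows = list(aggregates = nrow(agg$aggregates),
                contrasts = nrow(cm$contrasts),
                profile = nrow(profile),
                composite = nrow(composite)),
    pi0 = as.list(agg$pi0),
    flags_by_indicator = as.list(
      table(factor(profile$indicator[profile$flag != "none"], levels = 1:6)))
  )

  bundle <- structure(list(emr = emr, flags = flags, aggregates = agg,
                           contrasts = cm$contrasts, models = cm$models,
                           profile = profile, funnel = funnel,
                           composite = composite, manifest = manifest,
                           config = config),
                      class = "qoc_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' Write all stage outputs of a run to CSV (+ JSON manifest)
#'
#' @param bundle a `qoc_bundle`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(bundle$aggregates$aggregates,
                     file.path(dir, "facility_indicators.csv"))
  if (nrow(bundle$contrasts)) {
    data.table::fwrite(bundle$contrasts,
                       file.path(dir, "adjusted_contrasts.csv"))
  }
  if (length(bundle$models)) {
    data.table::fwrite(
      data.table::rbindlist(lapply(bundle$models, coef.casemix_model)),
      file.path(dir, "casemix_coefficients.csv"))
  }
  data.table::fwrite(bundle$profile, file.path(dir, "profiling.csv"))
  data.table::fwrite(bundle$funnel$curves, file.path(dir, "funnel_curves.csv"))
  data.table::fwrite(bundle$funnel$points, file.path(dir, "funnel_points.csv"))
  data.table::fwrite(bundle$composite, file.path(dir, "composite.csv"))
  writeLines(jsonlite::toJSON(bundle$manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @export
print.qoc_bundle <- function(x, ...) {
  cat("<qoc_bundle>\n")
  print(x$emr)
  print(x$aggregates)
  print(x$profile)
  print(x$composite)
  invisible(x)
}
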