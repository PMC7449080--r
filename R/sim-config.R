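# Simulation configuration for the synthetic EMR generator.

#' Simulation configuration for the synthetic EMR generator
#'
#' Builds a validated configuration object describing the synthetic world:
#' number and size of facilities, national baseline failure proportions for
#' the six indicators, the magnitude of true between-facility variation
#' (over-dispersion) on the logit scale, planted outlier facilities, and the
#' case-mix model linking patient covariates to the continuity-of-care
#' outcomes. Defaults emulate the scale and covariate structure of a
#' national HIV EMR: ~90 facilities of heterogeneous volume observed over a
#' 22-month window, with patient demographics and baseline clinical
#' covariates matching published national summaries (age 36.7 (13.3),
#' 63.5% female, BMI 22.1 (4.1), WHO stage and marital-status frequencies,
#' facility travel time 67.6 (67.3) minutes).
#'
#' @param n_facilities number of facilities (default 90).
#' @param volume_range integer vector c(min, max): patients per facility,
#'   drawn uniformly. Defaults give a national cohort of roughly 65,000
#'   patients across 90 facilities.
#' @param baseline_rates length-6 numeric in (0,1): national failure
#'   proportions for indicators 1-6 (test-and-start, viral load, MMS,
#'   timely pick-up, 6-month retention in non-pregnant adults, 6-month
#'   retention in pregnant women).
#' @param overdispersion_sd standard deviation(s) of the true facility
#'   effects on the logit scale, recycled to length 6. The default encodes
#'   the empirical pattern for this class of data: marked between-facility
#'   heterogeneity on the process-of-care indicators, mild residual
#'   heterogeneity on timely pick-up, and none on the case-mix-adjusted
#'   retention indicators.
#' @param patient_re_sd sd of the patient-level random effect on the logit
#'   of per-prescription late pick-up (indicator 4); induces the
#'   intra-patient correlation that makes indicator 4 over-dispersed even
#'   when facility effects are absent.
#' @param planted_outliers `data.frame(facility, indicator, shift)`: logit
#'   shifts added to the named facility/indicator cells (positive = more
#'   failure = low performer).
#' @param casemix_effects named numeric vector of log-odds effects of
#'   engineered covariate terms on the continuity outcomes (indicators
#'   4-6): `age10` (per 10 years above 36.7), `male`, `bmi5` (per 5 kg/m2
#'   above 22.1), `who4` (WHO stage 4), `travel30` (per 30 minutes travel),
#'   `slope` (per unit of facility slope above 3.2). Terms are centered
#'   across the generated population so the national mean stays at the
#'   baseline rate.
#' @param casemix_heterogeneity scalar >= 0 multiplying the facility-level
#'   covariate-composition shifts (mean patient age, WHO stage-4 share).
#'   0 removes all case-mix differences between facilities beyond sampling.
#' @param frac_new_dx fraction of patients newly diagnosed inside the
#'   observation window (the denominator pool for indicators 1, 5, 6).
#' @param mms_frac fraction of ART patients on multi-month scripting.
#' @param window character length-2, ISO dates for the observation window.
#' @param vl_eligibility_lag,vl_recency_window,grace_days indicator
#'   parameters passed through to evaluation (days).
#' @param missing_rate missing-at-random rate applied to BMI (the only
#'   covariate allowed to be missing in the synthetic world).
#' @param seed integer seed; all generator randomness derives from it.
#'
#' @return an object of class `qoc_sim_config` (a validated list).
#' @seealso [generate_facilities()], [generate_patients()], [simulate_emr()]
#' @export
sim_config <- function(n_facilities = 90,
                       volume_range = c(100, 1400),
                       baseline_rates = c(test_and_start = 0.25,
                                          viral_load = 0.45,
                                          mms_appropriate = 0.10,
                                          timely_pickup = 0.20,
                                          retention_adult = 0.20,
                                          retention_pregnant = 0.20),
                       overdispersion_sd = c(0.5, 0.5, 0.5, 0.15, 0, 0),
                       patient_re_sd = 0.5,
                       planted_outliers = NULL,
                       casemix_effects = c(age10 = -0.12, male = 0.15,
                                           bmi5 = -0.10, who4 = 0.30,
                                           travel30 = 0.10, slope = 0.05),
                       casemix_heterogeneity = 1,
                       frac_new_dx = 0.35,
                       mms_frac = 0.40,
                       window = c("2016-06-01", "2018-03-31"),
                       vl_eligibility_lag = 180,
                       vl_recency_window = 365,
                       grace_days = 30,
                       missing_rate = 0.05,
                       seed = 20160601) {
  if (length(n_facilities) != 1 || is.na(n_facilities) || n_facilities < 1) {
    config_error("n_facilities", "must be a single integer >= 1")
  }
  if (length(volume_range) != 2 || any(is.na(volume_range)) ||
      volume_range[1] < 1 || volume_range[2] < volume_range[1]) {
    config_error("volume_range", "must be c(min, max) with 1 <= min <= max")
  }
  baseline_rates <- rep_len(unname(baseline_rates), 6)
  check_prob(baseline_rates, "baseline_rates")
  overdispersion_sd <- rep_len(overdispersion_sd, 6)
  if (any(is.na(overdispersion_sd)) || any(overdispersion_sd < 0)) {
    config_error("overdispersion_sd", "must be >= 0")
  }
  if (length(patient_re_sd) != 1 || is.na(patient_re_sd) || patient_re_sd < 0) {
    config_error("patient_re_sd", "must be a single value >= 0")
  }
  if (!is.null(planted_outliers)) {
    planted_outliers <- as.data.frame(planted_outliers)
    need <- c("facility", "indicator", "shift")
    if (!all(need %in% names(planted_outliers))) {
      config_error("planted_outliers",
                   "needs columns facility, indicator, shift")
    }
    if (any(planted_outliers$facility < 1) ||
        any(planted_outliers$facility > n_facilities)) {
      config_error("planted_outliers", "facility index out of range")
    }
    if (!all(planted_outliers$indicator %in% 1:6)) {
      config_error("planted_outliers", "indicator must be in 1..6")
    }
  }
  check_prob(frac_new_dx, "frac_new_dx")
  check_prob(mms_frac, "mms_frac")
  check_prob(missing_rate, "missing_rate", open = FALSE)
  window <- as.Date(window)
  if (length(window) != 2 || any(is.na(window)) || window[2] <= window[1]) {
    config_error("window", "must be two ordered ISO dates")
  }
  if (casemix_heterogeneity < 0) {
    config_error("casemix_heterogeneity", "must be >= 0")
  }
  seed <- as.integer(seed)
  if (is.na(seed)) config_error("seed", "must be an integer")

  cfg <- list(
    n_facilities = as.integer(n_facilities),
    volume_range = as.integer(volume_range),
    baseline_rates = stats::setNames(baseline_rates, indicator_names()),
    overdispersion_sd = stats::setNames(overdispersion_sd, indicator_names()),
    patient_re_sd = patient_re_sd,
    planted_outliers = planted_outliers,
    casemix_effects = casemix_effects,
    casemix_heterogeneity = casemix_heterogeneity,
    frac_new_dx = frac_new_dx,
    mms_frac = mms_frac,
    window = window,
    vl_eligibility_lag = as.integer(vl_eligibility_lag),
    vl_recency_window = as.integer(vl_recency_window),
    grace_days = as.integer(grace_days),
    missing_rate = missing_rate,
    seed = seed,
    # population covariate targets (overridable by editing the object)
    covariates = list(
      age_mean = 36.7, age_sd = 13.3, age_min = 15,
      p_female = 0.635, p_male = 0.3613, p_gender_missing = 0.0037,
      p_pregnant_given_female = 0.459,
      bmi_mean = 22.1, bmi_sd = 4.1, bmi_min = 13,
      who_probs = c(0.281, 0.217, 0.225, 0.277),
      marital_probs = c(0.503, 0.130, 0.182, 0.185),
      travel_meanlog = 3.8693, travel_sdlog = 0.8299,
      slope_shape = 2.1157, slope_rate = 0.6612,
      dept_levels = c("Ouest", "Nord", "Sud", "Artibonite", "Nord Ouest",
                      "Nippes", "Sud Est", "Nord Est", "Grand Anse"),
      dept_probs = c(0.416, 0.192, 0.093, 0.090, 0.064,
                     0.040, 0.031, 0.044, 0.031),
      cat_levels = c("Univ Hosp", "Dep Hosp", "Other hosp",
                     "HCR", "CAL", "CSL/disp"),
      cat_probs = c(0.076, 0.418, 0.010, 0.200, 0.281, 0.015),
      # year-of-initiation profile for patients already on ART before the
      # window opens (renormalized over pre-window years)
      old_year_levels = 2004:2016,
      old_year_probs = c(0.001, 0.004, 0.011, 0.019, 0.031, 0.033, 0.031,
                         0.049, 0.074, 0.093, 0.112, 0.109, 0.072)
    )
  )
  class(cfg) <- "qoc_sim_config"
  cfg
}

#' @export
print.qoc_sim_config <- function(x, ...) {
  cat("<qoc_sim_config>\n")
  cat(sprintf("  facilities: %d (volume %d-%d)\n", x$n_facilities,
              x$volume_range[1], x$volume_range[2]))
  cat(sprintf("  window: %s .. %s\n", x$window[1], x$window[2]))
  cat("  baseline failure rates:",
      paste(sprintf("%s=%.2f", substr(indicator_names(), 1, 12),
                    x$baseline_rates), collapse = " "), "\n")
  cat("  facility-effect sd (logit):",
      paste(sprintf("%.2f", x$overdispersion_sd), collapse = " "), "\n")
  n_out <- if (is.null(x$planted_outliers)) 0 else nrow(x$planted_outliers)
  cat(sprintf("  planted outliers: %d; seed: %d\n", n_out, x$seed))
  invisible(x)
}
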