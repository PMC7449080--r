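# Shared fixtures and small configuration builders for the test suite.
# Everything is generated in code; no stored data.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Case-mix formula for small simulated worlds: at a few dozen facilities
# the facility-level categorical covariates (department, category) are
# near-saturated and can absorb a planted facility effect outright (a
# singleton department is an exact facility dummy), so planted-outlier
# scenarios adjust on patient-level covariates plus the continuous
# facility context only.
patient_level_formula <-
  ~ age + gender + factor(marital_status) + bmi + factor(who_stage) +
    factor(year_art_initiation) + travel_time + slope

# A small, fast world with the default structure.
small_config <- function(seed = 101, ...) {
  sim_config(n_facilities = 8, volume_range = c(80, 200), seed = seed, ...)
}

# A strict null world: no facility effects, no case-mix effects, no
# patient random effect, homogeneous covariate mix. Every indicator's true
# facility probability equals its baseline rate (indicator 4 conditional
# on the retention enforcement accounted for in the truth table).
null_config <- function(seed = 1, n_facilities = 8,
                        volume_range = c(200, 400), ...) {
  sim_config(n_facilities = n_facilities, volume_range = volume_range,
             overdispersion_sd = 0, patient_re_sd = 0,
             casemix_effects = c(age10 = 0), casemix_heterogeneity = 0,
             seed = seed, ...)
}

# Build a qoc_emr + qoc_flags pair from a hand-made patient table and a
# per-patient outcome, for direct tests of the case-mix machinery.
manual_casemix_data <- function(patients, failure, indicator = 5,
                                trials = NULL) {
  n <- nrow(patients)
  fac_ids <- unique(patients$facility_id)
  emr <- structure(list(
    patients = data.table::as.data.table(patients),
    dispenses = data.table::data.table(patient_id = character(),
                                       pickup_date = as.Date(character()),
                                       days_supplied = integer(),
                                       multi_month = logical(),
                                       stable = logical()),
    labs = data.table::data.table(patient_id = character(),
                                  test_date = as.Date(character())),
    facilities = data.table::data.table(
      facility_id = fac_ids,
      department = "Ouest", category = "HCR",
      travel_time = 60, slope = 3, volume = as.integer(table(
        factor(patients$facility_id, levels = fac_ids)))),
    truth = NULL, config = NULL,
    window = as.Date(c("2016-06-01", "2018-03-31"))), class = "qoc_emr")
  nm <- qocprofile:::indicator_names()[indicator]
  flags <- stats::setNames(vector("list", 6), qocprofile:::indicator_names())
  if (indicator == 4) {
    stopifnot(!is.null(trials))
    # expand to one pseudo-event row per trial
    idx <- rep(seq_len(n), trials)
    evn <- sequence(trials)
    fl <- data.table::data.table(
      facility_id = patients$facility_id[idx],
      unit_id = paste0(patients$patient_id[idx], ":", evn),
      failure = unlist(lapply(seq_len(n), function(i)
        rep(c(TRUE, FALSE), c(failure[i], trials[i] - failure[i])))))
  } else {
    fl <- data.table::data.table(facility_id = patients$facility_id,
                                 unit_id = patients$patient_id,
                                 failure = as.logical(failure))
  }
  for (k in qocprofile:::indicator_names()) {
    flags[[k]] <- data.table::data.table(facility_id = character(),
                                         unit_id = character(),
                                         failure = logical())
  }
  flags[[nm]] <- fl
  flags$params <- indicator_params(emr$window)
  class(flags) <- "qoc_flags"
  list(emr = emr, flags = flags)
}

# Minimal patient table with sensible defaults, overridable per column.
make_patients <- function(n, facility_id = "F001", who_stage = 1L,
                          age = 35, gender = "female", marital_status = 0L,
                          pregnant_postpartum = FALSE, bmi = 22,
                          year_art_initiation = 2016L) {
  data.table::data.table(
    patient_id = sprintf("P%05d", seq_len(n)),
    facility_id = facility_id, age = age, gender = gender,
    marital_status = marital_status,
    pregnant_postpartum = pregnant_postpartum, bmi = bmi,
    who_stage = who_stage,
    hiv_diagnosis_date = as.Date("2016-07-01"),
    art_start_date = as.Date("2016-07-10"),
    year_art_initiation = year_art_initiation)
}
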