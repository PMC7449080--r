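# Indicator engine: per-unit failure flags for the six quality-of-care
# indicators, and aggregation to per-facility failure counts.
#
# Failure is always the event being counted (non-compliance, late pick-up,
# non-retention), so every indicator points the same way: higher = worse.
# Units differ by indicator: patients for 1, 2, 5, 6; prescriptions for 4;
# multi-month prescriptions for 3. Outcomes that cannot be ascertained
# inside the observation window are excluded from denominators, never
# counted as failures.

#' Evaluation parameters for the indicator engine
#'
#' @param window length-2 observation window (ISO dates or Date).
#' @param ttt_window_days "1 month" window for test-and-start (days).
#' @param grace_days refill grace window (days), inclusive of the boundary.
#' @param vl_eligibility_lag_days days on ART before a patient is expected
#'   to have viral-load monitoring.
#' @param vl_recency_window_days a viral-load test older than this many
#'   days (relative to the window end) no longer counts as up to date.
#' @param retention_target_days nominal day-on-ART at which 6-month
#'   retention is assessed (182 = 6 x ~30.4 days).
#' @return a list of class `qoc_indicator_params`.
#' @export
indicator_params <- function(window,
                             ttt_window_days = 30,
                             grace_days = 30,
                             vl_eligibility_lag_days = 180,
                             vl_recency_window_days = 365,
                             retention_target_days = 182) {
  structure(list(window = as.Date(window),
                 ttt_window_days = as.integer(ttt_window_days),
                 grace_days = as.integer(grace_days),
                 vl_eligibility_lag_days = as.integer(vl_eligibility_lag_days),
                 vl_recency_window_days = as.integer(vl_recency_window_days),
                 retention_target_days = as.integer(retention_target_days)),
            class = "qoc_indicator_params")
}

#' Indicator 1: ART initiation within one month of diagnosis
#'
#' @param diagnosis_date,art_start_date Date vectors; `art_start_date` may
#'   be NA (never started).
#' @param window_days compliance window in days (default 30).
#' @return logical failure flags (TRUE = out of compliance).
#' @export
eval_test_and_start <- function(diagnosis_date, art_start_date,
                                window_days = 30) {
  diagnosis_date <- as.Date(diagnosis_date)
  art_start_date <- as.Date(art_start_date)
  both <- !is.na(art_start_date) & !is.na(diagnosis_date)
  if (any(both & art_start_date < diagnosis_date)) {
    stop("data integrity: ART start date precedes HIV diagnosis date",
         call. = FALSE)
  }
  is.na(art_start_date) |
    as.integer(art_start_date - diagnosis_date) > window_days
}

#' Indicator 2: up to date with viral-load testing (one patient)
#'
#' @param art_start_date Date scalar.
#' @param test_dates Date vector of the patient's viral-load tests.
#' @param as_of_date assessment date.
#' @param eligibility_lag_days minimum days on ART before eligibility.
#' @param recency_window_days how recent a test must be.
#' @return `NA` if the patient is not yet eligible, else a logical failure
#'   flag. Tests dated before ART start are ignored with a warning.
#' @export
eval_vl_up_to_date <- function(art_start_date, test_dates, as_of_date,
                               eligibility_lag_days = 180,
                               recency_window_days = 365) {
  art_start_date <- as.Date(art_start_date)
  as_of_date <- as.Date(as_of_date)
  test_dates <- as.Date(test_dates)
  if (as_of_date < art_start_date) {
    stop("as-of date precedes ART start", call. = FALSE)
  }
  if (as.integer(as_of_date - art_start_date) < eligibility_lag_days) {
    return(NA)
  }
  bad <- !is.na(test_dates) & test_dates < art_start_date
  if (any(bad)) {
    warning(sprintf("%d viral-load test(s) before ART start ignored",
                    sum(bad)), call. = FALSE)
    test_dates <- test_dates[!bad]
  }
  !any(test_dates >= as_of_date - recency_window_days &
         test_dates <= as_of_date, na.rm = TRUE)
}

#' Indicator 3: appropriateness of a multi-month prescription
#'
#' @param multi_month,stable logical vectors per dispense event.
#' @return logical: TRUE = inappropriate MMS (multi-month to an unstable
#'   patient); FALSE = guideline-concordant; NA = not applicable (not a
#'   multi-month prescription, excluded from the denominator).
#' @export
eval_mms_appropriate <- function(multi_month, stable) {
  ifelse(multi_month, multi_month & !stable, NA)
}

#' Indicator 4: timely pick-up after an expected refill date
#'
#' @param expected_date Date vector of expected refill dates.
#' @param next_pickup_date first pickup on/after the expected date (NA if
#'   the patient never returned).
#' @param grace_days grace window (inclusive).
#' @return logical failure flags.
#' @export
eval_timely_pickup <- function(expected_date, next_pickup_date,
                               grace_days = 30) {
  expected_date <- as.Date(expected_date)
  next_pickup_date <- as.Date(next_pickup_date)
  !(!is.na(next_pickup_date) &
      next_pickup_date >= expected_date &
      as.integer(next_pickup_date - expected_date) <= grace_days)
}

#' Indicators 5/6: 6-month retention for one patient
#'
#' The expected refill nearest to ART start + `target_days` is located on
#' the patient's realized dispense schedule (expected refill = pickup date
#' + days supplied); the patient fails if no pickup falls inside that
#' refill's grace window. A patient with no dispense events at all never
#' returned and fails.
#'
#' @param art_start_date Date scalar.
#' @param pickup_dates,days_supplied the patient's dispense history.
#' @param grace_days grace window (inclusive).
#' @param target_days nominal retention horizon in days (default 182).
#' @return logical failure flag.
#' @export
eval_retention_6m <- function(art_start_date, pickup_dates, days_supplied,
                              grace_days = 30, target_days = 182) {
  if (length(pickup_dates) == 0) return(TRUE)
  art_start_date <- as.Date(art_start_date)
  pickup_dates <- as.Date(pickup_dates)
  expected <- as.integer(pickup_dates - art_start_date) + days_supplied
  anchor <- expected[which.min(abs(expected - target_days))]
  day <- as.integer(pickup_dates - art_start_date)
  !any(day >= anchor & day <= anchor + grace_days)
}

#' Compute per-unit failure flags for all six indicators
#'
#' Applies the six indicator definitions to an EMR bundle and returns the
#' per-unit (patient or prescription) failure flags with facility
#' attribution. Denominators follow the ascertainability rule: a unit
#' enters only if its outcome window closes inside the observation window.
#'
#' @param emr a `qoc_emr` bundle ([simulate_emr()] or [read_emr()]).
#' @param params an [indicator_params()] object; defaults to the bundle's
#'   observation window with standard parameters.
#' @return an object of class `qoc_flags`: a list of six `data.table`s
#'   (columns `facility_id`, `unit_id`, `failure`) plus the params.
#' @export
compute_indicators <- function(emr, params = NULL) {
  stopifnot(inherits(emr, "qoc_emr"))
  if (is.null(params)) {
    cfg <- emr$config
    params <- indicator_params(
      window = emr$window,
      grace_days = cfg$grace_days %||% 30,
      vl_eligibility_lag_days = cfg$vl_eligibility_lag %||% 180,
      vl_recency_window_days = cfg$vl_recency_window %||% 365)
  }
  ws <- params$window[1]; we <- params$window[2]
  W <- as.integer(we - ws)
  grace <- params$grace_days
  p <- data.table::as.data.table(emr$patients)
  d <- data.table::as.data.table(emr$dispenses)
  labs <- data.table::as.data.table(emr$labs)

  both <- !is.na(p$art_start_date) & !is.na(p$hiv_diagnosis_date)
  if (any(both & p$art_start_date < p$hiv_diagnosis_date)) {
    stop("data integrity: ART start date precedes HIV diagnosis date",
         call. = FALSE)
  }

  ## indicator 1 ----------------------------------------------------------
  e1 <- p[!is.na(hiv_diagnosis_date) & hiv_diagnosis_date >= ws &
            as.integer(we - hiv_diagnosis_date) >= params$ttt_window_days]
  f1 <- e1[, .(facility_id, unit_id = patient_id,
               failure = eval_test_and_start(hiv_diagnosis_date,
                                             art_start_date,
                                             params$ttt_window_days))]

  ## indicator 2 ----------------------------------------------------------
  e2 <- p[!is.na(art_start_date) &
            as.integer(we - art_start_date) >= params$vl_eligibility_lag_days]
  nbad <- labs[p, on = "patient_id"][!is.na(test_date) &
                                       !is.na(art_start_date) &
                                       test_date < art_start_date, .N]
  if (nbad > 0) {
    warning(sprintf("%d viral-load test(s) before ART start ignored", nbad),
            call. = FALSE)
  }
  valid_tests <- labs[p[, .(patient_id, art_start_date)], on = "patient_id"][
    !is.na(test_date) & test_date >= art_start_date]
  recent <- valid_tests[test_date >= we - params$vl_recency_window_days &
                          test_date <= we, unique(patient_id)]
  f2 <- e2[, .(facility_id, unit_id = patient_id,
               failure = !(patient_id %in% recent))]

  ## dispense bookkeeping (integer day offsets) ---------------------------
  d <- d[p[, .(patient_id, facility_id, art_start_date,
               pregnant_postpartum)], on = "patient_id", nomatch = NULL]
  data.table::setorder(d, patient_id, pickup_date)
  d[, day := as.integer(pickup_date - ws)]
  d[, expected := day + days_supplied]
  d[, nxt := {
    fi <- findInterval(expected - 0.5, day)
    ifelse(fi + 1L <= .N, day[pmin(fi + 1L, .N)], NA_integer_)
  }, by = patient_id]

  ## indicator 3 ----------------------------------------------------------
  m <- d[multi_month == TRUE]
  f3 <- m[, .(facility_id,
              unit_id = paste0(patient_id, ":", format(pickup_date)),
              failure = multi_month & !stable)]

  ## indicator 4 ----------------------------------------------------------
  e4 <- d[expected + grace <= W]
  f4 <- e4[, .(facility_id,
               unit_id = paste0(patient_id, ":", format(pickup_date)),
               failure = is.na(nxt) | nxt > expected + grace)]

  ## indicators 5 and 6 ---------------------------------------------------
  # eligibility horizon: the anchor refill can drift up to half the
  # maximum renewal gap (45 + grace days) past day `target`, so the whole
  # band plus its grace window must close inside the observation window
  target <- params$retention_target_days
  horizon <- target + 2L * grace + 45L
  er <- p[!is.na(art_start_date) & art_start_date >= ws &
            as.integer(we - art_start_date) >= horizon]
  er[, start_day := as.integer(art_start_date - ws)]
  dr <- d[er[, .(patient_id, start_day)], on = "patient_id", nomatch = NULL]
  ret <- dr[, {
    anch <- expected[which.min(abs(expected - (start_day[1] + target)))]
    .(anchor = anch,
      failure = !any(day >= anch & day <= anch + grace))
  }, by = patient_id]
  er <- ret[er, on = "patient_id"]
  # never returned at all: certain failure, anchored at the nominal day
  er[is.na(anchor), `:=`(anchor = start_day + target, failure = TRUE)]
  # censor patients whose anchor grace window runs past the window end
  er <- er[anchor + grace <= W]
  f5 <- er[pregnant_postpartum == FALSE | is.na(pregnant_postpartum),
           .(facility_id, unit_id = patient_id, failure)]
  f6 <- er[pregnant_postpartum == TRUE,
           .(facility_id, unit_id = patient_id, failure)]

  structure(list(test_and_start = f1, viral_load = f2, mms_appropriate = f3,
                 timely_pickup = f4, retention_adult = f5,
                 retention_pregnant = f6, params = params),
            class = "qoc_flags")
}

#' Aggregate per-unit failure flags to facility-level counts
#'
#' Collapses the per-unit flags to one row per facility and indicator
#' (failures, denominator, observed failure proportion), and computes the
#' national pooled failure proportion `pi0` per indicator (total failures /
#' total denominator across facilities; the funnel target under H0).
#' Facilities present in `facilities` but with no eligible units carry
#' denominator 0 and an undefined proportion.
#'
#' @param flags a `qoc_flags` object from [compute_indicators()].
#' @param facilities optional facility roster (to include zero-denominator
#'   facilities).
#' @return an object of class `qoc_aggregates`: list with `aggregates`
#'   (`data.table`: `facility_id`, `indicator`, `failures`, `denominator`,
#'   `proportion`) and `pi0` (named length-6 vector).
#' @export
aggregate_indicators <- function(flags, facilities = NULL) {
  stopifnot(inherits(flags, "qoc_flags"))
  nms <- indicator_names()
  long <- data.table::rbindlist(lapply(seq_along(nms), function(k) {
    dt <- flags[[nms[k]]]
    if (nrow(dt) == 0) {
      return(data.table::data.table(facility_id = character(),
                                    indicator = integer(),
                                    failure = logical()))
    }
    data.table::data.table(facility_id = dt$facility_id, indicator = k,
                           failure = dt$failure)
  }))
  agg <- long[, .(failures = sum(failure), denominator = .N),
              by = .(facility_id, indicator)]
  fac_ids <- if (!is.null(facilities)) unique(facilities$facility_id)
             else unique(agg$facility_id)
  grid <- data.table::CJ(facility_id = fac_ids, indicator = 1:6)
  agg <- agg[grid, on = c("facility_id", "indicator")]
  agg[is.na(denominator), `:=`(failures = 0L, denominator = 0L)]
  agg[, proportion := ifelse(denominator > 0, failures / denominator,
                             NA_real_)]
  agg[, indicator_name := nms[indicator]]
  data.table::setorder(agg, indicator, facility_id)
  pi0 <- agg[denominator > 0,
             .(pi0 = sum(failures) / sum(denominator)), by = indicator]
  pi0v <- stats::setNames(rep(NA_real_, 6), nms)
  pi0v[pi0$indicator] <- pi0$pi0
  structure(list(aggregates = agg[], pi0 = pi0v), class = "qoc_aggregates")
}

#' @export
print.qoc_aggregates <- function(x, ...) {
  cat("<qoc_aggregates>\n")
  cat(sprintf("  %d facilities x 6 indicators\n",
              length(unique(x$aggregates$facility_id))))
  cat("  pooled failure proportions (pi0):\n")
  print(round(x$pi0, 4))
  invisible(x)
}
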