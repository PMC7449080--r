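# CSV input/output and schema validation. The CSV schema written by the
# generator doubles as the adapter contract for real EMR extracts.

emr_schema <- function() {
  list(
    patients = list(
      required = c("patient_id", "facility_id", "age", "gender",
                   "marital_status", "pregnant_postpartum", "bmi",
                   "who_stage", "hiv_diagnosis_date", "art_start_date",
                   "year_art_initiation"),
      date = c("hiv_diagnosis_date", "art_start_date")
    ),
    dispenses = list(
      required = c("patient_id", "pickup_date", "days_supplied",
                   "multi_month", "stable"),
      date = "pickup_date"
    ),
    labs = list(required = c("patient_id", "test_date"), date = "test_date"),
    facilities = list(
      required = c("facility_id", "department", "category", "travel_time",
                   "slope", "volume"),
      date = character()
    )
  )
}

#' Write a synthetic EMR bundle to CSV
#'
#' Writes `patients.csv`, `dispenses.csv`, `labs.csv`, `facilities.csv`
#' and `ground_truth.csv` (ISO-8601 dates throughout).
#'
#' @param emr a `qoc_emr` object from [simulate_emr()].
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_emr <- function(emr, dir) {
  stopifnot(inherits(emr, "qoc_emr"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(emr$patients, file.path(dir, "patients.csv"))
  data.table::fwrite(emr$dispenses, file.path(dir, "dispenses.csv"))
  data.table::fwrite(emr$labs, file.path(dir, "labs.csv"))
  data.table::fwrite(emr$facilities, file.path(dir, "facilities.csv"))
  data.table::fwrite(emr$truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

validation_error <- function(report) {
  stop(structure(
    class = c("qoc_validation_error", "error", "condition"),
    list(message = paste0("EMR input validation failed:\n",
                          paste(report, collapse = "\n")),
         call = NULL, report = report)
  ))
}

#' Read (and validate) an EMR extract from CSV
#'
#' Reads the four-table CSV schema written by [write_emr()]. Column
#' presence, date parseability, and basic record-level invariants (days
#' supplied positive, WHO stage in 1..4, ART start not before diagnosis)
#' are checked; violations raise a `qoc_validation_error` carrying a
#' per-column report.
#'
#' @param dir directory containing `patients.csv`, `dispenses.csv`,
#'   `labs.csv`, `facilities.csv` (and optionally `ground_truth.csv`).
#' @param window optional length-2 observation window (ISO dates); defaults
#'   to the range of the data.
#' @return a `qoc_emr` object.
#' @export
read_emr <- function(dir, window = NULL) {
  sch <- emr_schema()
  report <- character()
  tabs <- list()
  for (nm in names(sch)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      report <- c(report, sprintf("%s: file missing (%s)", nm, path))
      next
    }
    dt <- data.table::fread(path, na.strings = c("", "NA"))
    miss <- setdiff(sch[[nm]]$required, names(dt))
    if (length(miss)) {
      report <- c(report, sprintf("%s: missing column(s) %s", nm,
                                  paste(miss, collapse = ", ")))
    }
    for (dc in intersect(sch[[nm]]$date, names(dt))) {
      v <- dt[[dc]]
      parsed <- as.Date(as.character(v), format = "%Y-%m-%d")
      if (any(!is.na(v) & is.na(parsed))) {
        report <- c(report, sprintf("%s$%s: unparseable ISO dates", nm, dc))
      }
      data.table::set(dt, j = dc, value = parsed)
    }
    tabs[[nm]] <- dt
  }
  if (length(report)) validation_error(report)

  p <- tabs$patients
  if (any(!is.na(p$who_stage) & !(p$who_stage %in% 1:4))) {
    report <- c(report, "patients$who_stage: values outside 1..4")
  }
  both <- !is.na(p$art_start_date) & !is.na(p$hiv_diagnosis_date)
  if (any(both & p$art_start_date < p$hiv_diagnosis_date)) {
    report <- c(report, "patients: art_start_date precedes hiv_diagnosis_date")
  }
  if (any(tabs$dispenses$days_supplied <= 0, na.rm = TRUE)) {
    report <- c(report, "dispenses$days_supplied: non-positive values")
  }
  orphan <- setdiff(tabs$dispenses$patient_id, p$patient_id)
  if (length(orphan)) {
    report <- c(report, sprintf("dispenses: %d events reference unknown patients",
                                length(orphan)))
  }
  if (length(report)) validation_error(report)

  if (is.null(window)) {
    window <- range(c(tabs$dispenses$pickup_date, p$hiv_diagnosis_date),
                    na.rm = TRUE)
  } else {
    window <- as.Date(window)
  }
  truth_path <- file.path(dir, "ground_truth.csv")
  truth <- if (file.exists(truth_path)) data.table::fread(truth_path) else NULL
  structure(list(patients = p, dispenses = tabs$dispenses, labs = tabs$labs,
                 facilities = tabs$facilities, truth = truth, config = NULL,
                 window = window),
            class = "qoc_emr")
}
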