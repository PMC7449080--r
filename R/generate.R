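# Synthetic EMR generator: facility roster, patient-level records,
# pharmacy dispense events, viral-load lab events, and ground truth.
#
# The generator writes the world the downstream statistics assume:
# facility effects are additive on the logit scale (logit-normal mixing),
# case-mix enters the continuity outcomes through a centered linear
# predictor, dispense events follow a renewal process (pickup + days
# supplied schedules the next expected refill), and per-event lateness is
# drawn with a patient-level random effect so timely pick-up behaves as a
# correlated repeated measure.

#' Generate a synthetic facility roster
#'
#' Draws `n_facilities` facilities with department and category labels,
#' travel time (log-normal), an opaque "slope" covariate (gamma), and a
#' patient volume uniform on `volume_range`.
#'
#' @param config a [sim_config()] object.
#' @return a `data.table` with one row per facility: `facility_id`,
#'   `department`, `category`, `travel_time`, `slope`, `volume`.
#' @export
generate_facilities <- function(config) {
  stopifnot(inherits(config, "qoc_sim_config"))
  cv <- config$covariates
  withr::with_seed(config$seed, {
    n <- config$n_facilities
    data.table::data.table(
      facility_id = sprintf("F%03d", seq_len(n)),
      department = sample(cv$dept_levels, n, TRUE, cv$dept_probs),
      category = sample(cv$cat_levels, n, TRUE, cv$cat_probs),
      travel_time = round(stats::rlnorm(n, cv$travel_meanlog, cv$travel_sdlog), 1),
      slope = round(stats::rgamma(n, cv$slope_shape, cv$slope_rate), 2),
      # avoid sample(x) scalar expansion when min == max
      volume = config$volume_range[1] +
        sample.int(config$volume_range[2] - config$volume_range[1] + 1L,
                   n, replace = TRUE) - 1L
    )
  })
}

# Facility-level latent draws: true logit-scale effects per indicator
# (including planted shifts) and case-mix composition shifts.
facility_latents <- function(roster, config) {
  n <- nrow(roster)
  withr::with_seed(derive_seed(config$seed, 1L), {
    u <- matrix(stats::rnorm(n * 6), n, 6) *
      rep(config$overdispersion_sd, each = n)
    shift <- matrix(0, n, 6)
    po <- config$planted_outliers
    if (!is.null(po) && nrow(po)) {
      for (r in seq_len(nrow(po))) {
        shift[po$facility[r], po$indicator[r]] <-
          shift[po$facility[r], po$indicator[r]] + po$shift[r]
      }
    }
    list(
      delta = u + shift,
      random = u,
      planted = shift,
      age_shift = stats::rnorm(n, 0, 3) * config$casemix_heterogeneity,
      who4_tilt = stats::rnorm(n, 0, 0.4) * config$casemix_heterogeneity
    )
  })
}

# Truncated-normal sampler via the inverse-CDF (vectorized in the mean).
rtnorm_min <- function(n, mean, sd, lower) {
  plo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (1 - plo), mean, sd)
}

# Location parameter such that the lower-truncated normal has the target
# mean (truncation pulls the realized mean above the location, so the
# location must sit below the target).
tnorm_location_for_mean <- function(target, sd, lower) {
  vapply(target, function(tg) {
    f <- function(mu) {
      a <- (lower - mu) / sd
      mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a)) - tg
    }
    stats::uniroot(f, c(tg - 4 * sd, tg + sd), tol = 1e-8)$root
  }, numeric(1))
}

#' Generate patient-level records, dispense events, labs, and ground truth
#'
#' Simulates the full synthetic EMR for a facility roster: demographics and
#' baseline clinical covariates, HIV diagnosis and ART start dates, a
#' renewal-process pharmacy dispense history, viral-load lab events, and a
#' ground-truth table giving each facility's true failure probability per
#' indicator together with its planted outlier label.
#'
#' Outcome construction guarantees, conditional on the drawn covariates:
#' process-indicator failures are Bernoulli draws at
#' `invlogit(logit(rate) + facility effect + planted shift)`; 6-month
#' retention failure probability equals
#' `invlogit(logit(rate) + casemix + facility effect + shift)` exactly, by
#' composing early drop-out (truncation of the dispense sequence) with
#' per-event late pick-up around the 6-month refill.
#'
#' @param roster a facility roster from [generate_facilities()].
#' @param config the [sim_config()] used to build the roster.
#' @return an object of class `qoc_emr`: a list with `data.table`s
#'   `patients`, `dispenses`, `labs`, `facilities`, `truth`, plus the
#'   `config` and the observation `window`.
#' @export
generate_patients <- function(roster, config) {
  stopifnot(inherits(config, "qoc_sim_config"))
  if (nrow(roster) == 0) config_error("n_facilities", "roster is empty")
  cv <- config$covariates
  lat <- facility_latents(roster, config)
  rates <- config$baseline_rates
  W <- as.integer(config$window[2] - config$window[1])
  grace <- config$grace_days

  withr::with_seed(derive_seed(config$seed, 2L), {
    nF <- nrow(roster)
    fidx <- rep(seq_len(nF), roster$volume)
    n <- length(fidx)
    pid <- sprintf("P%06d", seq_len(n))

    ## ---- covariates -----------------------------------------------------
    age_loc <- tnorm_location_for_mean(cv$age_mean + lat$age_shift,
                                       cv$age_sd, cv$age_min)
    age <- round(rtnorm_min(n, age_loc[fidx], cv$age_sd, cv$age_min), 1)
    gender <- sample(c("female", "male", "missing"), n, TRUE,
                     c(cv$p_female, cv$p_male, cv$p_gender_missing))
    pregnant <- gender == "female" &
      stats::runif(n) < cv$p_pregnant_given_female
    bmi_loc <- tnorm_location_for_mean(cv$bmi_mean, cv$bmi_sd, cv$bmi_min)
    bmi <- round(rtnorm_min(n, bmi_loc, cv$bmi_sd, cv$bmi_min), 1)
    bmi[stats::runif(n) < config$missing_rate] <- NA_real_
    marital <- sample(0:3, n, TRUE, cv$marital_probs)
    # WHO stage with a facility-level tilt on the stage-4 share
    p4who <- invlogit(logit(cv$who_probs[4]) + lat$who4_tilt[fidx])
    sc <- (1 - p4who) / (1 - cv$who_probs[4])
    c1 <- cv$who_probs[1] * sc
    c2 <- c1 + cv$who_probs[2] * sc
    c3 <- c2 + cv$who_probs[3] * sc
    uwho <- stats::runif(n)
    who <- 1L + (uwho > c1) + (uwho > c2) + (uwho > c3)

    new_dx <- stats::runif(n) < config$frac_new_dx

    ## ---- diagnosis and ART start dates (day offsets, 0 = window open) ---
    dx_day <- integer(n)
    start_day <- rep(NA_integer_, n)
    n_new <- sum(new_dx)
    dx_day[new_dx] <- sample(0:W, n_new, TRUE)
    # patients already on ART when the window opens
    n_old <- n - n_new
    yr <- sample(cv$old_year_levels, n_old, TRUE, cv$old_year_probs)
    yr_start <- as.integer(as.Date(sprintf("%d-01-01", yr)) - config$window[1])
    yr_len <- ifelse(yr == 2016L,
                     as.integer(as.Date("2016-05-31") -
                                  as.Date("2016-01-01")),
                     as.integer(as.Date(sprintf("%d-12-31", yr)) -
                                  as.Date(sprintf("%d-01-01", yr))))
    start_day[!new_dx] <- yr_start + floor(stats::runif(n_old) * (yr_len + 1))
    dx_day[!new_dx] <- start_day[!new_dx] - sample(0:180, n_old, TRUE)

    ## ---- indicator 1: test and start ------------------------------------
    p1 <- invlogit(logit(rates[1]) + lat$delta[fidx, 1])
    fail1 <- stats::runif(n) < p1
    ok1 <- new_dx & !fail1
    start_day[ok1] <- dx_day[ok1] + sample(0:30, sum(ok1), TRUE)
    late1 <- new_dx & fail1 & stats::runif(n) >= 0.4
    start_day[late1] <- dx_day[late1] + 31L +
      stats::rgeom(sum(late1), 1 / 45)
    start_day[new_dx & fail1 & !late1] <- NA_integer_
    start_day[!is.na(start_day) & start_day > W & new_dx] <- NA_integer_

    has_start <- !is.na(start_day)
    year_init <- rep(NA_integer_, n)
    year_init[has_start] <- as.integer(format(
      config$window[1] + start_day[has_start], "%Y"))

    ## ---- continuity linear predictor (case-mix), centered ---------------
    be <- config$casemix_effects
    term <- function(nm, v) if (nm %in% names(be)) be[[nm]] * v else 0
    xb <- term("age10", (age - cv$age_mean) / 10) +
      term("male", as.numeric(gender == "male")) +
      term("bmi5", ifelse(is.na(bmi), 0, (bmi - cv$bmi_mean) / 5)) +
      term("who4", as.numeric(who == 4L)) +
      term("travel30", roster$travel_time[fidx] / 30) +
      term("slope", roster$slope[fidx] - 3.2)
    xb <- xb - mean(xb)

    b_pat <- stats::rnorm(n, 0, config$patient_re_sd)
    p4 <- invlogit(logit(rates[4]) + xb + lat$delta[fidx, 4] + b_pat)

    ## ---- 6-month retention mechanics ------------------------------------
    # The 6-month outcome is ascertainable only when the whole band of
    # possible anchor refills (nearest expected refill to day 182 lies
    # within half the maximum renewal gap, 45 + grace days) closes inside
    # the window; this matches the engine's eligibility rule and keeps
    # censoring independent of the outcome.
    horizon <- 182L + 2L * grace + 45L
    elig_ret <- has_start & new_dx & start_day <= W - horizon
    kret <- ifelse(pregnant, 6L, 5L)
    p_ret <- invlogit(logit(rates[kret]) + xb +
                        lat$delta[cbind(fidx, kret)])
    # draw the outcome once and enforce it mechanically: failures stop
    # picking up before the anchor band (truncation), successes have every
    # band refill picked up on time (forcing); either way the realized
    # 6-month failure probability equals p_ret exactly
    ret_fail <- elig_ret & stats::runif(n) < p_ret
    trunc_flag <- ret_fail
    force_flag <- elig_ret & !ret_fail
    trunc_day <- sample(30:120, n, TRUE)

    ## ---- dispense renewal process ---------------------------------------
    on_art <- has_start & start_day <= W
    mms <- on_art & stats::runif(n) < config$mms_frac
    supplied <- ifelse(mms, 90L, 30L)
    idx <- which(on_art)
    first <- ifelse(new_dx[idx], start_day[idx],
                    floor(stats::runif(length(idx)) * supplied[idx]))
    ev <- vector("list", 32L)
    ev[[1]] <- data.table::data.table(i = idx, day = as.integer(first))
    act_i <- idx
    act_day <- as.integer(first)
    k <- 1L
    while (length(act_i) && k < 32L) {
      expected <- act_day + supplied[act_i]
      keep <- expected <= W &
        !(trunc_flag[act_i] & expected > start_day[act_i] + trunc_day[act_i])
      act_i <- act_i[keep]
      expected <- expected[keep]
      if (!length(act_i)) break
      # the realized refill nearest day 182 always lies within half of the
      # maximum renewal gap (90 + 2*grace) of day 182; forcing the whole
      # band keeps retained patients' 6-month outcome a certain success
      half <- 45L + grace
      since <- expected - start_day[act_i]
      forced <- force_flag[act_i] & !is.na(since) &
        since >= 182L - half & since <= 182L + half
      late <- !forced & stats::runif(length(act_i)) < p4[act_i]
      delay <- integer(length(act_i))
      delay[late] <- sample((grace + 1L):(2L * grace), sum(late), TRUE)
      delay[!late] <- sample(0:grace, sum(!late), TRUE)
      pickup <- expected + delay
      keep2 <- pickup <= W
      act_i <- act_i[keep2]
      act_day <- pickup[keep2]
      k <- k + 1L
      ev[[k]] <- data.table::data.table(i = act_i, day = act_day)
    }
    events <- data.table::rbindlist(ev[seq_len(k)])
    data.table::setorder(events, i, day)
    events[, `:=`(supplied = supplied[i], mm = mms[i])]

    # MMS appropriateness: per multi-month prescription
    p3ev <- invlogit(logit(rates[3]) + lat$delta[fidx[events$i], 3])
    fail3 <- events$mm & stats::runif(nrow(events)) < p3ev
    events[, stable := !fail3]

    ## ---- viral load lab events ------------------------------------------
    elig_vl <- has_start & (W - start_day) >= config$vl_eligibility_lag
    p2 <- invlogit(logit(rates[2]) + lat$delta[fidx, 2])
    fail2 <- stats::runif(n) < p2
    vl_ok <- which(elig_vl & !fail2)
    lo_t <- pmax(start_day[vl_ok], W - config$vl_recency_window)
    t_ok <- lo_t + floor(stats::runif(length(vl_ok)) * (W - lo_t + 1))
    vl_stale <- which(elig_vl & fail2 &
                        stats::runif(n) < 0.5 &
                        start_day <= W - config$vl_recency_window - 1L)
    hi_t <- W - config$vl_recency_window - 1L
    t_stale <- start_day[vl_stale] + floor(
      stats::runif(length(vl_stale)) * (hi_t - start_day[vl_stale] + 1))
    labs <- data.table::data.table(
      i = c(vl_ok, vl_stale), day = as.integer(c(t_ok, t_stale)))
    data.table::setorder(labs, i, day)

    ## ---- ground truth ----------------------------------------------------
    # indicator 4 truth: per evaluated prescription (expected refill
    # ascertainable), accounting for retention-driven truncation (certain
    # failure) and forcing (certain on-time pick-up)
    events[, expected := day + supplied]
    evald <- events[expected <= W - grace]
    ptrue <- p4[evald$i]
    # an evaluated event is a certain failure when generation stopped at
    # its expected refill: the next expected (= this event's expected)
    # exceeded the truncation day
    tstop <- trunc_flag[evald$i] &
      (evald$expected > start_day[evald$i] + trunc_day[evald$i])
    sincee <- evald$expected - start_day[evald$i]
    half <- 45L + grace
    ffor <- force_flag[evald$i] & sincee >= 182L - half &
      sincee <= 182L + half
    ptrue[ffor] <- 0
    ptrue[tstop] <- 1
    truth4 <- data.table::data.table(f = fidx[evald$i], p = ptrue)[
      , .(true_prob = mean(p), denom = .N), by = f]

    truth56 <- data.table::data.table(
      f = fidx[elig_ret], k = kret[elig_ret], p = p_ret[elig_ret])[
        , .(true_prob = mean(p), denom = .N), by = .(f, k)]

    truth <- data.table::CJ(f = seq_len(nF), indicator = 1:6)
    truth[, true_prob := NA_real_]
    for (kk in 1:3) {
      truth[indicator == kk,
            true_prob := invlogit(logit(rates[kk]) + lat$delta[f, kk])]
    }
    truth[truth4, on = c(f = "f"),
          true_prob := ifelse(indicator == 4L, i.true_prob, true_prob)]
    truth[truth56[k == 5L], on = c(f = "f"),
          true_prob := ifelse(indicator == 5L, i.true_prob, true_prob)]
    truth[truth56[k == 6L], on = c(f = "f"),
          true_prob := ifelse(indicator == 6L, i.true_prob, true_prob)]
    truth[, facility_effect := lat$delta[cbind(f, indicator)]]
    truth[, planted_shift := lat$planted[cbind(f, indicator)]]
    truth[, label := data.table::fcase(planted_shift > 0, "low_performer",
                                       planted_shift < 0, "high_performer",
                                       default = "none")]
    truth[, `:=`(facility_id = roster$facility_id[f],
                 indicator_name = indicator_names()[indicator])]
    truth[, f := NULL]
    data.table::setcolorder(truth, c("facility_id", "indicator",
                                     "indicator_name", "true_prob",
                                     "facility_effect", "planted_shift",
                                     "label"))

    ## ---- assemble output tables -----------------------------------------
    origin <- config$window[1]
    patients <- data.table::data.table(
      patient_id = pid,
      facility_id = roster$facility_id[fidx],
      age = age,
      gender = gender,
      marital_status = marital,
      pregnant_postpartum = pregnant,
      bmi = bmi,
      who_stage = who,
      hiv_diagnosis_date = origin + dx_day,
      art_start_date = origin + start_day,
      year_art_initiation = year_init
    )
    dispenses <- data.table::data.table(
      patient_id = pid[events$i],
      pickup_date = origin + events$day,
      days_supplied = events$supplied,
      multi_month = events$mm,
      stable = events$stable
    )
    labdt <- data.table::data.table(
      patient_id = pid[labs$i],
      test_date = origin + labs$day
    )

    structure(list(patients = patients, dispenses = dispenses, labs = labdt,
                   facilities = data.table::copy(roster), truth = truth,
                   config = config, window = config$window),
              class = "qoc_emr")
  })
}

#' Simulate a complete synthetic EMR extract
#'
#' Convenience wrapper: generates the facility roster and all patient-level
#' tables from one configuration, optionally writing the five CSV files
#' (facilities, patients, dispenses, labs, ground truth) to a directory.
#'
#' @param config a [sim_config()] object.
#' @param dir optional output directory for CSV export.
#' @return a `qoc_emr` object (invisibly if `dir` is given).
#' @export
simulate_emr <- function(config = sim_config(), dir = NULL) {
  roster <- generate_facilities(config)
  emr <- generate_patients(roster, config)
  if (!is.null(dir)) {
    write_emr(emr, dir)
    return(invisible(emr))
  }
  emr
}

#' @export
print.qoc_emr <- function(x, ...) {
  cat("<qoc_emr>\n")
  cat(sprintf("  %d facilities, %d patients, %d dispense events, %d lab tests\n",
              nrow(x$facilities), nrow(x$patients), nrow(x$dispenses),
              nrow(x$labs)))
  cat(sprintf("  window: %s .. %s\n", x$window[1], x$window[2]))
  invisible(x)
}
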