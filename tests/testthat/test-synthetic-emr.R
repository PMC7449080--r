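# Synthetic EMR generator: roster, determinism, record-level invariants,
# ground-truth exactness, and the null-world binomial property.

test_that("facility roster honours the configuration", {
  cfg <- sim_config(seed = 3)
  roster <- generate_facilities(cfg)
  expect_equal(nrow(roster), 90)
  expect_true(all(roster$volume >= cfg$volume_range[1] &
                    roster$volume <= cfg$volume_range[2]))
  expect_true(all(roster$department %in% cfg$covariates$dept_levels))
  expect_true(all(roster$category %in% cfg$covariates$cat_levels))
  expect_equal(length(unique(roster$facility_id)), 90)

  # degenerate single-facility config
  tiny <- sim_config(n_facilities = 1, volume_range = c(5, 5), seed = 3)
  r1 <- generate_facilities(tiny)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$volume, 5L)
})

test_that("invalid configurations raise errors naming the field", {
  expect_error(sim_config(baseline_rates = c(0.2, 1.2, 0.1, 0.2, 0.2, 0.2)),
               "baseline_rates", class = "qoc_config_error")
  expect_error(sim_config(volume_range = c(0, 10)), "volume_range",
               class = "qoc_config_error")
  expect_error(sim_config(overdispersion_sd = -1), "overdispersion_sd",
               class = "qoc_config_error")
  expect_error(sim_config(n_facilities = 0), "n_facilities",
               class = "qoc_config_error")
  expect_error(sim_config(planted_outliers = data.frame(facility = 99,
                                                        indicator = 1,
                                                        shift = 1),
                          n_facilities = 10),
               "planted_outliers", class = "qoc_config_error")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 11)
  a <- simulate_emr(cfg)
  b <- simulate_emr(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$dispenses, b$dispenses)
  expect_identical(a$labs, b$labs)
  expect_identical(a$facilities, b$facilities)
  expect_identical(a$truth, b$truth)
  # and a different seed changes the draw
  c2 <- simulate_emr(small_config(seed = 12))
  expect_false(identical(a$patients, c2$patients))
})

test_that("patient records satisfy the domain invariants", {
  emr <- simulate_emr(small_config(seed = 21))
  p <- emr$patients
  expect_true(all(p$age >= 15))
  expect_true(all(p$who_stage %in% 1:4))
  expect_true(all(p$marital_status %in% 0:3))
  expect_true(all(p$gender %in% c("female", "male", "missing")))
  expect_true(all(!p$pregnant_postpartum | p$gender == "female"))
  both <- !is.na(p$art_start_date)
  expect_true(all(p$art_start_date[both] >= p$hiv_diagnosis_date[both]))
  expect_true(all(p$facility_id %in% emr$facilities$facility_id))

  d <- emr$dispenses
  expect_true(all(d$days_supplied > 0))
  expect_true(all(d$patient_id %in% p$patient_id))
  # pickup dates strictly increasing within patient
  gaps <- d[, diff(as.integer(pickup_date)), by = patient_id]$V1
  expect_true(all(gaps > 0))
})

test_that("null world: every true probability equals its baseline rate", {
  cfg <- null_config(seed = 5)
  emr <- simulate_emr(cfg)
  tr <- emr$truth
  for (k in c(1, 2, 3, 5, 6)) {
    expect_equal(tr[tr$indicator == k, ]$true_prob,
                 rep(unname(cfg$baseline_rates[k]), 8), tolerance = 1e-12)
  }
  # indicator 4's truth absorbs the retention enforcement; it stays close
  # to (but need not equal) the baseline per-event rate
  expect_true(all(abs(tr[tr$indicator == 4, ]$true_prob -
                        cfg$baseline_rates[4]) < 0.05))
  expect_true(all(tr$label == "none"))
})

test_that("planted logit shifts move the truth by the closed form", {
  shift <- data.frame(facility = c(2L, 3L), indicator = c(5L, 1L),
                      shift = c(2, -1.5))
  cfg <- null_config(seed = 9, planted_outliers = shift)
  emr <- simulate_emr(cfg)
  tr <- emr$truth
  p5 <- tr[tr$indicator == 5 & tr$facility_id == "F002", ]$true_prob
  expect_equal(p5, invlogit(logit(0.20) + 2), tolerance = 1e-12)
  p1 <- tr[tr$indicator == 1 & tr$facility_id == "F003", ]$true_prob
  expect_equal(p1, invlogit(logit(0.25) - 1.5), tolerance = 1e-12)
  expect_equal(tr[tr$indicator == 5 & tr$facility_id == "F002", ]$label,
               "low_performer")
  expect_equal(tr[tr$indicator == 1 & tr$facility_id == "F003", ]$label,
               "high_performer")
  # ground-truth labels partition facilities into exactly the planted sets
  expect_equal(sum(tr$label != "none"), 2L)
})

test_that("covariate distributions match their population targets", {
  # homogeneous case-mix so the marginals are the population targets
  cfg <- sim_config(n_facilities = 20, volume_range = c(500, 500),
                    casemix_heterogeneity = 0, seed = 31)
  emr <- generate_patients(generate_facilities(cfg), cfg)
  p <- emr$patients
  n <- nrow(p)
  expect_equal(n, 10000L)
  # three standard errors around the configured targets
  expect_lt(abs(mean(p$age) - 36.7), 3 * 13.3 / sqrt(n))
  expect_lt(abs(mean(p$gender == "female") - 0.635),
            3 * sqrt(0.635 * 0.365 / n))
  expect_lt(abs(mean(p$bmi, na.rm = TRUE) - 22.1), 3 * 4.1 / sqrt(n))
  expect_lt(abs(mean(p$who_stage == 4) - 0.277),
            3 * sqrt(0.277 * 0.723 / n))
  expect_lt(abs(mean(p$pregnant_postpartum) - 0.291),
            3 * sqrt(0.291 * 0.709 / n))
})

test_that("null world is binomial: goodness-of-fit across 100 replicates", {
  # chi-square GOF of per-facility failure counts: against the known
  # baseline rate for the exactly-binomial indicators (1,2,3,5,6), and
  # against the pooled rate (homogeneity / no over-dispersion) for
  # indicator 4, whose marginal rate absorbs the retention enforcement.
  reps <- 100
  rej_exact <- matrix(FALSE, reps, 5)
  rej_disp <- logical(reps)
  for (r in seq_len(reps)) {
    cfg <- null_config(seed = 1000 + r, n_facilities = 6,
                       volume_range = c(150, 250))
    emr <- simulate_emr(cfg)
    agg <- aggregate_indicators(compute_indicators(emr), emr$facilities)
    a <- agg$aggregates
    for (j in seq_along(c(1, 2, 3, 5, 6))) {
      k <- c(1, 2, 3, 5, 6)[j]
      ak <- a[a$indicator == k & a$denominator > 0, ]
      p0 <- cfg$baseline_rates[k]
      x2 <- sum((ak$failures - ak$denominator * p0)^2 /
                  (ak$denominator * p0 * (1 - p0)))
      rej_exact[r, j] <- stats::pchisq(x2, df = nrow(ak)) > 0.99
    }
    a4 <- a[a$indicator == 4 & a$denominator > 0, ]
    ph <- sum(a4$failures) / sum(a4$denominator)
    x2 <- sum((a4$failures - a4$denominator * ph)^2 /
                (a4$denominator * ph * (1 - ph)))
    rej_disp[r] <- stats::pchisq(x2, df = nrow(a4) - 1) > 0.99
  }
  # allow the nominal 1% false-rejection rate plus 3 MC standard errors
  allow <- 0.01 + 3 * sqrt(0.01 * 0.99 / reps)
  for (j in 1:5) expect_lte(mean(rej_exact[, j]), allow)
  expect_lte(mean(rej_disp), allow)
})

test_that("CSV round trip preserves the tables", {
  dir <- withr::local_tempdir()
  emr <- simulate_emr(small_config(seed = 41), dir = dir)
  expect_true(all(file.exists(file.path(dir, c(
    "patients.csv", "dispenses.csv", "labs.csv", "facilities.csv",
    "ground_truth.csv")))))
  back <- read_emr(dir)
  expect_equal(nrow(back$patients), nrow(emr$patients))
  expect_equal(back$patients$art_start_date, emr$patients$art_start_date)
  expect_equal(back$dispenses$pickup_date, emr$dispenses$pickup_date)
})

test_that("schema violations produce a per-column validation error", {
  dir <- withr::local_tempdir()
  simulate_emr(small_config(seed = 42), dir = dir)
  p <- data.table::fread(file.path(dir, "patients.csv"))
  p$who_stage <- NULL
  data.table::fwrite(p, file.path(dir, "patients.csv"))
  err <- tryCatch(read_emr(dir), qoc_validation_error = function(e) e)
  expect_s3_class(err, "qoc_validation_error")
  expect_match(conditionMessage(err), "who_stage")
})
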