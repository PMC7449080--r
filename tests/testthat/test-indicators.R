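# Indicator engine: the six per-unit rules and facility aggregation.

test_that("test-and-start rule follows the 30-day window", {
  expect_false(eval_test_and_start("2017-05-01", "2017-05-20"))
  expect_false(eval_test_and_start("2017-05-01", "2017-05-01"))  # same day
  expect_false(eval_test_and_start("2017-05-01", "2017-05-31"))  # boundary
  expect_true(eval_test_and_start("2017-05-01", "2017-07-01"))   # 61 days
  expect_true(eval_test_and_start("2017-05-01", NA))             # never
  expect_error(eval_test_and_start("2017-05-01", "2017-04-30"),
               "integrity")
  # vectorized
  expect_equal(eval_test_and_start(rep("2017-05-01", 3),
                                   c("2017-05-10", "2017-06-15", NA)),
               c(FALSE, TRUE, TRUE))
})

test_that("viral-load recency rule handles eligibility and stale tests", {
  # 546 days between test and as-of: stale
  expect_true(eval_vl_up_to_date("2016-01-01", "2016-10-01", "2018-03-31",
                                 recency_window_days = 365))
  # 181 days before as-of: still within the 365-day recency window
  expect_false(eval_vl_up_to_date("2016-01-01", "2017-10-01", "2018-03-31",
                                  recency_window_days = 365))
  expect_false(eval_vl_up_to_date("2016-01-01", "2018-03-31", "2018-03-31"))
  # 75 days on ART < 180-day lag: not eligible
  expect_true(is.na(eval_vl_up_to_date("2018-01-15", as.Date(character()),
                                       "2018-03-31")))
  # tests before ART start are ignored with a warning
  expect_warning(
    res <- eval_vl_up_to_date("2017-01-01", "2016-12-01", "2018-03-31"),
    "before ART start")
  expect_true(res)
  expect_error(eval_vl_up_to_date("2018-04-02", "2018-01-01", "2018-03-31"),
               "precedes ART start")
})

test_that("MMS appropriateness distinguishes failure from not-applicable", {
  expect_true(eval_mms_appropriate(TRUE, FALSE))
  expect_false(eval_mms_appropriate(TRUE, TRUE))
  expect_true(is.na(eval_mms_appropriate(FALSE, TRUE)))
  expect_equal(eval_mms_appropriate(c(TRUE, TRUE, FALSE),
                                    c(FALSE, TRUE, FALSE)),
               c(TRUE, FALSE, NA))
})

test_that("timely pick-up uses the inclusive 30-day grace window", {
  expect_false(eval_timely_pickup("2017-03-01", "2017-03-25"))
  expect_false(eval_timely_pickup("2017-03-01", "2017-03-01"))  # on the day
  expect_false(eval_timely_pickup("2017-03-01", "2017-03-31"))  # boundary
  expect_true(eval_timely_pickup("2017-03-01", "2017-04-05"))   # 35 days
  expect_true(eval_timely_pickup("2017-03-01", NA))
})

test_that("6-month retention anchors the refill nearest day 182", {
  # continuous on-time 90-day refills: anchor at day 180 is covered
  start <- as.Date("2017-01-01")
  pickups <- start + c(0, 90, 180, 270)
  expect_false(eval_retention_6m(start, pickups, rep(90L, 4)))
  # never returned at all
  expect_true(eval_retention_6m(start, as.Date(character()), integer()))
  # stopped after the first 30-day refill: anchor is the dangling refill
  expect_true(eval_retention_6m(start, start + c(0, 30), c(30L, 30L)))
  # 30-day cycle, anchor refill picked up 40 days late
  pick <- start + c(seq(0, 150, 30), 220)
  expect_true(eval_retention_6m(start, pick, rep(30L, 7)))
})

test_that("aggregation counts, pools and preserves conservation", {
  emr <- simulate_emr(small_config(seed = 55))
  flags <- compute_indicators(emr)
  agg <- aggregate_indicators(flags, emr$facilities)
  a <- agg$aggregates
  expect_true(all(a$failures <= a$denominator))
  expect_true(all(a$failures >= 0))
  nm <- c("test_and_start", "viral_load", "mms_appropriate",
          "timely_pickup", "retention_adult", "retention_pregnant")
  for (k in 1:6) {
    fl <- flags[[nm[k]]]
    expect_equal(sum(a[a$indicator == k, ]$failures), sum(fl$failure))
    expect_equal(sum(a[a$indicator == k, ]$denominator), nrow(fl))
    # pi0 is the pooled (unit-weighted) proportion
    expect_equal(unname(agg$pi0[k]), mean(fl$failure))
  }
  # indicators 5 and 6 denominators are disjoint patient sets
  expect_length(intersect(flags$retention_adult$unit_id,
                          flags$retention_pregnant$unit_id), 0)
  # indicator 3 units are a subset of indicator 4's universe (multi-month
  # prescriptions only)
  expect_lte(sum(a[a$indicator == 3, ]$denominator),
             nrow(emr$dispenses[emr$dispenses$multi_month, ]))
})

test_that("hand-built micro-cohort aggregates exactly", {
  # facility A: flags {T,T,F,F,F}; facility B: {T,F,F,F,F}
  fl <- structure(list(
    test_and_start = data.table::data.table(
      facility_id = rep(c("A", "B"), each = 5),
      unit_id = sprintf("P%02d", 1:10),
      failure = c(TRUE, TRUE, FALSE, FALSE, FALSE,
                  TRUE, FALSE, FALSE, FALSE, FALSE)),
    viral_load = data.table::data.table(facility_id = character(),
                                        unit_id = character(),
                                        failure = logical()),
    mms_appropriate = data.table::data.table(facility_id = character(),
                                             unit_id = character(),
                                             failure = logical()),
    timely_pickup = data.table::data.table(facility_id = character(),
                                           unit_id = character(),
                                           failure = logical()),
    retention_adult = data.table::data.table(facility_id = character(),
                                             unit_id = character(),
                                             failure = logical()),
    retention_pregnant = data.table::data.table(facility_id = character(),
                                                unit_id = character(),
                                                failure = logical()),
    params = NULL), class = "qoc_flags")
  agg <- aggregate_indicators(fl)
  a <- agg$aggregates[agg$aggregates$indicator == 1, ]
  expect_equal(a$failures, c(2L, 1L))
  expect_equal(a$denominator, c(5L, 5L))
  expect_equal(a$proportion, c(0.4, 0.2))
  expect_equal(unname(agg$pi0[1]), 0.3)  # pooled 3/10
  # facility with no eligible units: denominator 0, undefined proportion
  fac <- data.table::data.table(facility_id = c("A", "B", "C"))
  agg2 <- aggregate_indicators(fl, fac)
  c_row <- agg2$aggregates[agg2$aggregates$facility_id == "C" &
                            agg2$aggregates$indicator == 1, ]
  expect_equal(c_row$denominator, 0L)
  expect_true(is.na(c_row$proportion))
  expect_equal(unname(agg2$pi0[1]), 0.3)  # unchanged by the empty facility
})

test_that("engine failure rates track the generator's ground truth", {
  # moderately large single world; compare observed proportions with the
  # per-facility true probabilities on the binomial z scale
  cfg <- null_config(seed = 77, n_facilities = 5,
                     volume_range = c(1500, 1500))
  emr <- simulate_emr(cfg)
  agg <- aggregate_indicators(compute_indicators(emr), emr$facilities)
  m <- merge(agg$aggregates, emr$truth, by = c("facility_id", "indicator"))
  m <- m[m$denominator > 0, ]
  zf <- (m$proportion - m$true_prob) /
    sqrt(m$true_prob * (1 - m$true_prob) / m$denominator)
  expect_true(all(abs(zf) < 4))
  expect_lt(abs(mean(zf)), 3 / sqrt(nrow(m)))
})
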