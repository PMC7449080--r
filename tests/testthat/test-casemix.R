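# Case-mix adjustment: logistic MLE, indirect standardization, logit
# contrasts, and calibration.

test_that("2x2 table recovers the closed-form logistic coefficient", {
  # exposed (WHO stage 4): 30/100 fail; unexposed (stage 1): 10/100 fail
  pts <- make_patients(200, who_stage = rep(c(4L, 1L), each = 100))
  fail <- c(rep(c(TRUE, FALSE), c(30, 70)), rep(c(TRUE, FALSE), c(10, 90)))
  md <- manual_casemix_data(pts, fail, indicator = 5)
  fit <- fit_casemix(md$flags, md$emr, 5, formula = ~ factor(who_stage))
  b <- coef(fit)
  # log odds ratio: log[(30/70)/(10/90)]
  expect_equal(b$estimate[b$term == "factor(who_stage)4"],
               log((30 / 70) / (10 / 90)), tolerance = 1e-6)
  expect_equal(b$estimate[b$term == "(Intercept)"], log(10 / 90),
               tolerance = 1e-6)
})

test_that("intercept-only model predicts the pooled rate for everyone", {
  pts <- make_patients(50, facility_id = rep(c("F001", "F002"), 25))
  fail <- rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), 10)   # pooled 0.2
  md <- manual_casemix_data(pts, fail, indicator = 5)
  fit <- fit_casemix(md$flags, md$emr, 5, formula = ~ 1)
  ex <- expected_facility_proportion(fit, md$flags, md$emr)
  expect_equal(ex$expected, rep(0.2, 2), tolerance = 1e-9)
})

test_that("expected facility proportion is the mean of predictions", {
  pts <- make_patients(400, who_stage = rep(c(1L, 4L), 200),
                       facility_id = rep(c("F001", "F002"), each = 200))
  set.seed(4)
  p_true <- ifelse(pts$who_stage == 4, 0.4, 0.2)
  fail <- runif(400) < p_true
  md <- manual_casemix_data(pts, fail, indicator = 5)
  fit <- fit_casemix(md$flags, md$emr, 5, formula = ~ factor(who_stage))
  fr <- qocprofile:::casemix_frame(md$flags, md$emr, 5)
  pred <- qocprofile:::predict_casemix(fit, fr)
  ex <- expected_facility_proportion(fit, md$flags, md$emr)
  for (f in c("F001", "F002")) {
    expect_equal(ex$expected[ex$facility_id == f],
                 mean(pred[fr$facility_id == f]), tolerance = 1e-12)
  }
  # two units predicted 0.2 and 0.4 average to 0.3
  expect_equal(mean(c(0.2, 0.4)), 0.3)
})

test_that("all-same outcome raises an estimation error", {
  pts <- make_patients(20)
  md <- manual_casemix_data(pts, rep(FALSE, 20), indicator = 5)
  expect_error(fit_casemix(md$flags, md$emr, 5, formula = ~ 1),
               class = "qoc_estimation_error")
})

test_that("unseen categorical level maps to the reference with a warning", {
  pts <- make_patients(100, who_stage = rep(c(1L, 4L), 50))
  set.seed(5)
  md <- manual_casemix_data(pts, runif(100) < 0.3, indicator = 5)
  fit <- fit_casemix(md$flags, md$emr, 5, formula = ~ factor(who_stage))
  nd <- data.frame(who_stage = c(1L, 2L, 4L))  # stage 2 never seen
  expect_warning(pr <- qocprofile:::predict_casemix(fit, nd),
                 "unseen level")
  expect_equal(pr[2], pr[1])  # mapped to reference (stage 1)
})

test_that("logit contrast evaluates the stated formulas", {
  cc <- logit_contrast(failures = 30, denominator = 100, expected = 0.2)
  expect_equal(cc$y, logit(0.3) - logit(0.2), tolerance = 1e-12)
  expect_equal(cc$y, 0.5390, tolerance = 1e-3)
  expect_equal(cc$s, 1 / sqrt(100 * 0.2 * 0.8), tolerance = 1e-12)
  expect_equal(cc$s, 0.25)
  # observed equals expected: zero contrast
  cc0 <- logit_contrast(30, 100, 0.3)
  expect_equal(cc0$y, 0, tolerance = 1e-12)
  # boundary continuity correction keeps y finite
  cb <- logit_contrast(0, 50, 0.2, c = 0.5)
  expect_equal(cb$observed, 0)
  expect_equal(cb$y, logit(0.5 / 51) - logit(0.2), tolerance = 1e-12)
  expect_true(is.finite(cb$y))
  # empty denominator dropped with a message
  expect_message(cz <- logit_contrast(c(3, 0), c(10, 0), c(0.3, 0.3)),
                 "excluded")
  expect_equal(nrow(cz), 1)
})

test_that("s decreases as 1/sqrt(n) for fixed expected proportion", {
  n <- c(10, 40, 90, 160, 1000)
  s <- logit_contrast(rep(1, 5), n, rep(0.25, 5))$s
  expect_true(all(diff(s) < 0))
  expect_equal(s[1] / s[2], sqrt(40 / 10), tolerance = 1e-12)
})

test_that("indirect standardization is calibrated on the training data", {
  emr <- simulate_emr(sim_config(n_facilities = 12,
                                 volume_range = c(200, 500), seed = 61))
  flags <- compute_indicators(emr)
  agg <- aggregate_indicators(flags, emr$facilities)
  suppressMessages(cm <- casemix_contrasts(flags, emr, agg))
  ct <- cm$contrasts
  for (k in 4:6) {
    ck <- ct[ct$indicator == k, ]
    # denominator-weighted mean of (observed - expected) vanishes when the
    # model has an intercept (score equation of the logistic MLE)
    expect_lt(abs(sum(ck$n * (ck$observed - ck$expected)) / sum(ck$n)), 1e-6)
  }
})

test_that("known coefficient is recovered across replicates", {
  # beta = 0.8 on WHO stage 4; 50 replicates; the 95% Wald CI should cover
  # the truth in >= 90% of replicates
  reps <- 50
  n <- 4000
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    set.seed(700 + r)
    who <- sample(c(1L, 4L), n, TRUE)
    eta <- qocprofile::logit(0.2) + 0.8 * (who == 4L)
    pts <- make_patients(n, who_stage = who,
                         facility_id = sample(c("F001", "F002"), n, TRUE))
    md <- manual_casemix_data(pts, runif(n) < invlogit(eta), indicator = 5)
    fit <- fit_casemix(md$flags, md$emr, 5, formula = ~ factor(who_stage))
    sm <- summary(fit$fit)$coefficients
    est <- sm["factor(who_stage)4", 1]; se <- sm["factor(who_stage)4", 2]
    covered[r] <- abs(est - 0.8) <= qnorm(0.975) * se
  }
  expect_gte(mean(covered), 0.9)
})

test_that("indicator 4 uses per-patient aggregated binomial trials", {
  pts <- make_patients(30, who_stage = rep(c(1L, 4L), 15))
  trials <- rep(4L, 30)
  fails <- ifelse(pts$who_stage == 4, 2L, 1L)
  md <- manual_casemix_data(pts, fails, indicator = 4, trials = trials)
  fit <- fit_casemix(md$flags, md$emr, 4, formula = ~ factor(who_stage))
  b <- coef(fit)
  expect_equal(b$estimate[b$term == "factor(who_stage)4"],
               log((2 / 2) / (1 / 3)), tolerance = 1e-6)
  ex <- expected_facility_proportion(fit, md$flags, md$emr)
  expect_equal(ex$n, 120L)  # 30 patients x 4 prescriptions
})
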