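# Case-mix adjustment (indirect standardization) for the continuity-of-care
# indicators: national logistic regressions on patient covariates (facility
# identity is never a predictor), facility-level expected failure
# proportions, and logit-scale observed-vs-expected contrasts with
# normal-approximation standard errors.

casemix_covariates <- function() {
  c("age", "gender", "marital_status", "pregnant_postpartum", "bmi",
    "who_stage", "year_art_initiation", "travel_time", "slope",
    "department", "category")
}

default_casemix_formula <- function(indicator) {
  rhs <- c("age", "gender", "factor(marital_status)",
           if (indicator == 4) "pregnant_postpartum",
           "bmi", "factor(who_stage)", "factor(year_art_initiation)",
           "travel_time", "slope", "department", "category")
  stats::reformulate(rhs, response = NULL)
}

# Drop RHS terms that are constant in the data at hand (e.g. gender in
# the pregnant-women cohort, or a single initiation year in a short
# simulated window): a single-level factor would abort model.matrix().
prune_constant_terms <- function(formula, df) {
  terms <- attr(stats::terms(formula), "term.labels")
  keep <- vapply(terms, function(tm) {
    v <- tryCatch(eval(str2lang(tm), envir = df), error = function(e) NULL)
    is.null(v) || length(unique(v[!is.na(v)])) >= 2
  }, logical(1))
  if (!all(keep)) {
    message("case-mix model: dropping constant term(s) ",
            paste(terms[!keep], collapse = ", "))
  }
  if (all(!keep)) return(stats::reformulate("1"))
  stats::reformulate(terms[keep])
}

# Build the patient-level modelling frame for one continuity indicator:
# outcome (failures/trials), covariates, and facility attribution.
casemix_frame <- function(flags, emr, indicator) {
  nm <- indicator_names()[indicator]
  fl <- flags[[nm]]
  if (indicator == 4) {
    fl <- data.table::as.data.table(fl)
    fl[, patient_id := sub(":.*$", "", unit_id)]
    unit <- fl[, .(failures = sum(failure), trials = .N), by = patient_id]
  } else {
    unit <- data.table::data.table(patient_id = fl$unit_id,
                                   failures = as.integer(fl$failure),
                                   trials = 1L)
  }
  p <- data.table::as.data.table(emr$patients)
  fac <- data.table::as.data.table(emr$facilities)
  df <- p[unit, on = "patient_id", nomatch = NULL]
  df <- fac[, .(facility_id, travel_time, slope, department,
                category)][df, on = "facility_id"]
  # mean-impute missing BMI (flagging would add a covariate the national
  # summary table does not carry)
  if (anyNA(df$bmi)) df[is.na(bmi), bmi := mean(df$bmi, na.rm = TRUE)]
  df[]
}

#' Fit a national case-mix model for a continuity-of-care indicator
#'
#' Maximum-likelihood logistic regression of the failure outcome on patient
#' demographics and baseline clinical covariates plus facility-level
#' context covariates (travel time, slope, department, category). Facility
#' identity is deliberately excluded: the model describes what outcome a
#' patient with given covariates would have at the average facility, which
#' is what indirect standardization compares against. Indicator 4 is fitted
#' on per-patient aggregated trials (`cbind(failures, successes)`), so each
#' patient contributes one weighted observation regardless of prescription
#' count.
#'
#' Complete separation (or any divergence of the MLE) triggers a ridge
#' fallback (`glmnet`, alpha = 0, small lambda) with a warning; an outcome
#' with no variation at all is an estimation error.
#'
#' @param flags `qoc_flags` from [compute_indicators()].
#' @param emr the `qoc_emr` bundle the flags came from.
#' @param indicator 4, 5 or 6.
#' @param formula optional model formula (RHS over the Table-2 covariate
#'   set); defaults to the full covariate set.
#' @param ridge_lambda penalty used by the separation fallback.
#' @return an object of class `casemix_model`.
#' @export
fit_casemix <- function(flags, emr, indicator, formula = NULL,
                        ridge_lambda = 1e-3) {
  stopifnot(indicator %in% 4:6)
  df <- casemix_frame(flags, emr, indicator)
  if (nrow(df) == 0 || sum(df$failures) == 0 ||
      sum(df$failures) == sum(df$trials)) {
    stop(structure(class = c("qoc_estimation_error", "error", "condition"),
                   list(message = sprintf(
                     "indicator %d: outcome has no variation; cannot fit case-mix model",
                     indicator), call = NULL)))
  }
  formula <- formula %||% default_casemix_formula(indicator)
  formula <- prune_constant_terms(formula, df)
  full <- stats::update(formula, cbind(failures, trials - failures) ~ .)
  fit <- withCallingHandlers(
    stats::glm(full, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  method <- "ml"
  coefs <- stats::coef(fit)
  if (!fit$converged || any(abs(coefs[!is.na(coefs)]) > 15)) {
    if (requireNamespace("glmnet", quietly = TRUE)) {
      warning(sprintf(
        "indicator %d: separation detected; falling back to ridge (lambda = %g)",
        indicator, ridge_lambda), call. = FALSE)
      X <- stats::model.matrix(stats::terms(fit), df)[, -1, drop = FALSE]
      yb <- cbind(df$trials - df$failures, df$failures)
      rfit <- glmnet::glmnet(X, yb, family = "binomial", alpha = 0,
                             lambda = ridge_lambda, standardize = TRUE)
      fit$coefficients[] <- NA
      b <- as.numeric(rfit$beta)
      names(b) <- rownames(rfit$beta)
      fit$coefficients[names(b)] <- b
      fit$coefficients["(Intercept)"] <- rfit$a0
      method <- "ridge"
    } else {
      warning(sprintf(
        "indicator %d: possible separation and glmnet unavailable; using ML fit",
        indicator), call. = FALSE)
    }
  }
  structure(list(fit = fit, indicator = indicator, formula = formula,
                 xlevels = fit$xlevels, method = method),
            class = "casemix_model")
}

#' @export
print.casemix_model <- function(x, ...) {
  cat(sprintf("<casemix_model> indicator %d (%s), %d coefficients (%s)\n",
              x$indicator, indicator_names()[x$indicator],
              length(stats::coef(x$fit)), x$method))
  invisible(x)
}

#' Coefficient table of a case-mix model (for audit export)
#' @param object a `casemix_model`.
#' @param ... unused.
#' @return a `data.table` with `term` and `estimate`.
#' @export
coef.casemix_model <- function(object, ...) {
  b <- stats::coef(object$fit)
  data.table::data.table(indicator = object$indicator,
                         term = names(b), estimate = unname(b))
}

# Predict failure probabilities, mapping unseen categorical levels to the
# model's reference level (with a warning naming the variable).
predict_casemix <- function(model, newdata) {
  nd <- data.table::as.data.table(newdata)
  for (v in names(model$xlevels)) {
    raw <- sub("^factor\\((.*)\\)$", "\\1", v)
    if (!raw %in% names(nd)) next
    vals <- as.character(nd[[raw]])
    known <- model$xlevels[[v]]
    bad <- !is.na(vals) & !(vals %in% known)
    if (any(bad)) {
      warning(sprintf(
        "%d unseen level(s) of %s mapped to reference level '%s'",
        sum(bad), raw, known[1]), call. = FALSE)
      vals[bad] <- known[1]
      data.table::set(nd, j = raw, value = vals)
    }
  }
  as.numeric(stats::predict(model$fit, newdata = nd, type = "response"))
}

#' Facility-level expected failure proportions (indirect standardization)
#'
#' The expected proportion for a facility is the arithmetic mean of its
#' eligible units' predicted failure probabilities under the national
#' case-mix model (trials-weighted for indicator 4, where the unit is the
#' prescription).
#'
#' @param model a [fit_casemix()] model.
#' @param flags,emr the flags/EMR the facility denominators come from.
#' @return `data.table` with `facility_id`, `expected`, `n` (denominator in
#'   units of the indicator).
#' @export
expected_facility_proportion <- function(model, flags, emr) {
  df <- casemix_frame(flags, emr, model$indicator)
  df[, pred := predict_casemix(model, .SD)]
  df[, .(expected = sum(pred * trials) / sum(trials),
         n = sum(trials)), by = facility_id]
}

#' Logit-scale observed-vs-expected contrast with standard error
#'
#' Computes, per facility, `y = logit(p) - logit(E)` on the failure scale
#' (positive = more failure than the case-mix model expects) and the
#' normal-approximation standard error `s = 1 / sqrt(n * E * (1 - E))`,
#' which treats the expected proportion as known. A continuity correction
#' `(failures + c) / (n + 2c)` is applied only when the observed count sits
#' on the boundary (0 or n failures), keeping `y` finite without biasing
#' interior facilities.
#'
#' @param failures,denominator observed failure counts and denominators.
#' @param expected expected failure proportions in (0, 1).
#' @param c continuity-correction constant (default 0.5).
#' @return `data.table` with `observed`, `expected`, `y`, `s`, `n` (rows
#'   with `denominator == 0` are dropped with a message).
#' @export
logit_contrast <- function(failures, denominator, expected, c = 0.5) {
  keep <- denominator > 0
  if (any(!keep)) {
    message(sprintf("%d facility(ies) with empty denominator excluded from contrast",
                    sum(!keep)))
  }
  x <- failures[keep]; n <- denominator[keep]; E <- expected[keep]
  stopifnot(all(E > 0 & E < 1))
  p <- x / n
  boundary <- x == 0 | x == n
  ptilde <- ifelse(boundary, (x + c) / (n + 2 * c), p)
  data.table::data.table(
    observed = p, expected = E,
    y = logit(ptilde) - logit(E),
    s = 1 / sqrt(n * E * (1 - E)),
    n = n, kept = which(keep))
}

#' Case-mix-adjusted contrasts for indicators 4-6
#'
#' Fits (or reuses) the national case-mix models and assembles the
#' per-facility adjusted contrast table. With `adjust = FALSE` the expected
#' proportion is the national pooled proportion for every facility
#' (i.e. no case-mix adjustment), which is the correct comparator for
#' quantifying how much adjustment matters.
#'
#' @param flags,emr flags and EMR bundle.
#' @param aggregates a `qoc_aggregates` object (for observed counts).
#' @param indicators which continuity indicators (subset of 4:6).
#' @param adjust fit case-mix models (TRUE) or use the pooled proportion.
#' @param formula optional shared model formula override.
#' @param models optional pre-fitted list of `casemix_model`s keyed by
#'   indicator number (as character).
#' @return list with `contrasts` (`data.table`: `facility_id`, `indicator`,
#'   `observed`, `expected`, `y`, `s`, `n`) and `models`.
#' @export
casemix_contrasts <- function(flags, emr, aggregates, indicators = 4:6,
                              adjust = TRUE, formula = NULL, models = NULL) {
  stopifnot(inherits(aggregates, "qoc_aggregates"))
  agg <- aggregates$aggregates
  out <- list(); fitted <- list()
  for (k in indicators) {
    ak <- agg[indicator == k & denominator > 0]
    if (nrow(ak) == 0) next
    if (adjust) {
      mk <- models[[as.character(k)]] %||%
        fit_casemix(flags, emr, k, formula = formula)
      fitted[[as.character(k)]] <- mk
      ex <- expected_facility_proportion(mk, flags, emr)
      ak <- ex[ak, on = "facility_id"]
      ak[is.na(expected), expected := sum(ak$failures) / sum(ak$denominator)]
    } else {
      ak <- data.table::copy(ak)
      ak[, expected := aggregates$pi0[k]]
    }
    cc <- logit_contrast(ak$failures, ak$denominator, ak$expected)
    out[[as.character(k)]] <- data.table::data.table(
      facility_id = ak$facility_id[cc$kept], indicator = k,
      observed = cc$observed, expected = cc$expected,
      y = cc$y, s = cc$s, n = cc$n)
  }
  list(contrasts = data.table::rbindlist(out), models = fitted)
}
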