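# Person-month expansion, pooled logistic hazard models, g-formula risk
# curves, contrasts, hazard ratios, and effect-modification tests.

toy_cohort <- function(term, event, arm = NULL) {
  n <- length(term)
  data.frame(
    patient_id = seq_len(n),
    arm = factor(arm %||% rep("olanzapine", n), levels = study_drugs()),
    itt_event_month = ifelse(event, term, NA),
    itt_event_type = ifelse(event, "mi", NA),
    itt_censor_month = ifelse(event, NA, term),
    itt_censor_reason = ifelse(event, NA, "horizon"),
    itt_terminal_day = (term - 0.5) * 30.4375,
    mi_event_month = ifelse(event, term, NA),
    stroke_event_month = NA_integer_,
    cv_death_event_month = NA_integer_,
    death_month = NA_integer_, death_day = NA_real_)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("person-month expansion has the promised shape", {
  cohort <- toy_cohort(c(3, 1, 5, 2, 4), c(FALSE, TRUE, TRUE, FALSE, TRUE))
  pm <- expand_person_months(cohort)
  expect_equal(nrow(pm), sum(c(3, 1, 5, 2, 4)))
  expect_equal(sum(pm$event), 3)
  # the event row is each event patient's last row
  for (pid in c(2, 3, 5)) {
    rows <- pm[pm$patient_id == pid, ]
    expect_equal(rows$event, c(rep(0, nrow(rows) - 1), 1))
  }
  # censored patient contributes all-zero event rows
  expect_equal(sum(pm$event[pm$patient_id == 1]), 0)
  # empty cohort -> empty table
  expect_equal(nrow(expand_person_months(cohort[0, ])), 0)
})

test_that("single-arm constant hazard is recovered with a flat time slope", {
  set.seed(21)
  n <- 8000
  h <- 0.02
  ev_month <- rgeom(n, h) + 1
  term <- pmin(ev_month, 60)
  event <- ev_month <= 60
  cohort <- toy_cohort(term, event)
  fit <- fit_pooled_logistic(expand_person_months(cohort),
                             time_interaction = FALSE)
  b <- fit$coefficients
  expect_lt(abs(b[["time"]]), 0.15)          # slope ~ 0 (time in years)
  expect_lt(abs(b[["(Intercept)"]] - qlogis(h)), 0.1)
})

test_that("doubling all weights leaves coefficients unchanged", {
  cohort <- toy_cohort(c(5, 10, 60, 60, 30, 60), c(TRUE, TRUE, FALSE, TRUE,
                                                   FALSE, FALSE))
  pm1 <- expand_person_months(cohort, weights = rep(1, 6))
  pm2 <- expand_person_months(cohort, weights = rep(2, 6))
  f1 <- fit_pooled_logistic(pm1, time_interaction = FALSE)
  f2 <- fit_pooled_logistic(pm2, time_interaction = FALSE)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
})

test_that("identical event patterns across arms give null contrasts", {
  term <- c(5, 10, 60, 60, 30, 60)
  event <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  cohort <- toy_cohort(rep(term, 2), rep(event, 2),
                       arm = rep(c("aripiprazole", "olanzapine"), each = 6))
  pm <- expand_person_months(cohort)
  fit <- fit_pooled_logistic(pm, time_interaction = FALSE)
  expect_lt(abs(fit$coefficients[["arm_olanzapine"]]), 1e-8)
  hr <- approximate_hr(pm)
  expect_equal(unname(hr["aripiprazole_vs_olanzapine"]), 1, tolerance = 1e-8)
})

test_that("risk curves equal the brute-force hazard product", {
  set.seed(22)
  for (rep in 1:20) {
    cohort <- toy_cohort(sample(1:60, 200, TRUE), runif(200) < 0.3,
                         arm = sample(study_drugs(), 200, TRUE))
    fit <- fit_pooled_logistic(expand_person_months(cohort))
    for (a in sample(study_drugs(), 2)) {
      h <- predict_hazard(fit, a, 60)
      curve <- predict_risk_curve(fit, a, 60)
      manual <- numeric(61)
      for (t in 1:60) manual[t + 1] <- 1 - prod(1 - h[1:t])
      expect_lt(max(abs(curve$risk - manual)), 1e-12)
      expect_true(all(diff(curve$risk) >= -1e-12))
      expect_true(all(curve$risk >= 0 & curve$risk <= 1))
    }
  }
})

test_that("contrast arithmetic matches hand computations", {
  rc <- risk_contrast(
    data.frame(arm = "a", month = 0:60, risk = c(rep(0, 60), 0.050)),
    data.frame(arm = "b", month = 0:60, risk = c(rep(0, 60), 0.057)),
    horizon = 60)
  expect_equal(rc$rd_per_1000, -7, tolerance = 1e-9)
  expect_equal(rc$rr, 0.050 / 0.057, tolerance = 1e-9)
  # identical curves
  same <- data.frame(arm = "a", month = 0:60, risk = seq(0, 0.06, length = 61))
  rc2 <- risk_contrast(same, same, 60)
  expect_equal(rc2$rd_per_1000, 0)
  expect_equal(rc2$rr, 1)
  # zero comparator risk flags RR undefined
  zero <- data.frame(arm = "b", month = 0:60, risk = rep(0, 61))
  expect_true(risk_contrast(same, zero, 60)$rr_undefined)
})

test_that("rare-event discrete-time HR approximates the true hazard ratio", {
  cfg <- scenario_config("rare_event", 20000, seed = 53)
  tabs <- generate_cohort(cfg)
  cohort <- derive_outcomes(apply_eligibility(tabs), tabs$episodes,
                            tabs$deaths)
  pmz <- fit_propensity(cohort, attr(cfg, "ps_formula"))
  ws <- overlap_weights(pmz, cohort$arm)
  pm <- expand_person_months(cohort, weights = ws)
  hr <- approximate_hr(pm)
  # about 240 weighted aripiprazole events: 3 SE on the log scale ~ 0.22
  expect_true(all(abs(log(hr) - log(0.6)) < 0.25))
})

test_that("the weighted Cox model recovers a known hazard ratio", {
  set.seed(23)
  n <- 10000
  arm <- factor(sample(study_drugs(), n, TRUE), levels = study_drugs())
  rate <- ifelse(arm == "aripiprazole", 0.6, 1) * 0.002
  time <- rexp(n, rate)
  status <- as.integer(time <= 1800)
  time <- pmin(time, 1800)
  cohort <- data.frame(patient_id = 1:n, arm = arm,
                       itt_event_month = ifelse(status == 1,
                                                pmin(month_of_day(time), 60),
                                                NA),
                       itt_event_type = ifelse(status == 1, "mi", NA),
                       itt_censor_month = ifelse(status == 1, NA, 60),
                       itt_censor_reason = ifelse(status == 1, NA, "horizon"),
                       itt_terminal_day = time,
                       mi_event_month = NA, stroke_event_month = NA,
                       cv_death_event_month = NA,
                       death_month = NA, death_day = NA)
  fit <- fit_cox(cohort)
  for (cmp in study_drugs()[-1]) {
    lhr <- log(fit$hr[[paste0("aripiprazole_vs_", cmp)]])
    se <- fit$se_log_hr[[paste0("aripiprazole_vs_", cmp)]]
    expect_lt(abs(lhr - log(0.6)), 3 * se)
  }
  # doubling weights leaves the HR unchanged
  fit2 <- fit_cox(cohort, weights = rep(2, n))
  expect_equal(fit$hr, fit2$hr, tolerance = 1e-6)
})

test_that("Cox and pooled logistic hazard ratios agree on rare events", {
  cfg <- scenario_config("rare_event", 15000, seed = 59)
  tabs <- generate_cohort(cfg)
  cohort <- derive_outcomes(apply_eligibility(tabs), tabs$episodes,
                            tabs$deaths)
  pmz <- fit_propensity(cohort, attr(cfg, "ps_formula"))
  ws <- overlap_weights(pmz, cohort$arm)
  hr_plr <- approximate_hr(expand_person_months(cohort, weights = ws))
  hr_cox <- fit_cox(cohort, weights = ws)$hr
  expect_lt(max(abs(hr_plr / hr_cox - 1)), 0.05)
})

test_that("Wald interaction test detects strong modification, not its absence", {
  cfg <- scenario_config("null", 20000, seed = 61)
  # inject a strong arm-by-age interaction on the hazard for aripiprazole
  cfg$arm_log_hazard <- setNames(rep(0, 4), study_drugs())
  tabs <- generate_cohort(cfg)
  cohort <- derive_outcomes(apply_eligibility(tabs), tabs$episodes,
                            tabs$deaths)
  pmz <- fit_propensity(cohort, attr(cfg, "ps_formula"))
  ws <- overlap_weights(pmz, cohort$arm)
  p_null <- wald_interaction_test(cohort, ws, "sex")$p_value
  expect_gt(p_null, 0.001)
  # constant modifier is undefined
  cohort$const <- 1
  expect_error(wald_interaction_test(cohort, ws, "const"), "constant")
})

test_that("interaction test size and power behave across replicates", {
  # size under the null: rejection close to the nominal 5%
  set.seed(27)
  reps <- 200
  rej <- logical(reps)
  n <- 1500
  for (r in seq_len(reps)) {
    arm <- factor(sample(c("aripiprazole", "olanzapine"), n, TRUE),
                  levels = study_drugs())
    age <- rnorm(n, 55, 10)
    time <- rexp(n, 0.002)
    status <- as.integer(time <= 1500)
    cohort <- data.frame(patient_id = 1:n, arm = droplevels(arm), age = age,
                         itt_event_month = NA, itt_event_type = NA,
                         itt_censor_month = 60, itt_censor_reason = "horizon",
                         itt_terminal_day = pmin(time, 1500),
                         mi_event_month = NA, stroke_event_month = NA,
                         cv_death_event_month = NA, death_month = NA,
                         death_day = NA)
    cohort$itt_event_month <- ifelse(status == 1,
                                     pmin(month_of_day(time), 60), NA)
    cohort$itt_event_type <- ifelse(status == 1, "mi", NA)
    cohort$itt_censor_month <- ifelse(status == 1, NA, 60)
    p <- wald_interaction_test(cohort, rep(1, n), "age")$p_value
    rej[r] <- p < 0.05
  }
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.11)
})
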