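# Synthetic linked-cohort generator: degenerate configurations, closed-form
# oracles, missingness mechanics, and reproducibility contracts.

test_that("degenerate hazards produce the promised extremes", {
  cfg0 <- sim_config(n_patients = 300, seed = 1, baseline_hazard = 0,
                     noncv_death_hazard = 0,
                     eligibility_violations = c(late_smi = 0),
                     missingness_spec = list())
  tabs <- generate_cohort(cfg0)
  expect_equal(nrow(tabs$deaths), 0)
  expect_false(any(grepl("^I21|^I6", tabs$episodes$primary_icd10)))
  tr <- attr(tabs, "truth")
  expect_true(all(is.na(tr$mace_month)) && all(is.na(tr$noncv_death_month)))

  cfg1 <- sim_config(n_patients = 300, seed = 1, baseline_hazard = 0,
                     noncv_death_hazard = c(1, rep(0, 59)),
                     eligibility_violations = c(late_smi = 0),
                     missingness_spec = list())
  tabs1 <- generate_cohort(cfg1)
  tr1 <- attr(tabs1, "truth")
  expect_true(all(tr1$noncv_death_month == 1))
  expect_true(all(is.na(tr1$mace_month)))
  expect_equal(sort(tabs1$deaths$patient_id), 1:300)
})

test_that("a missing seed is rejected", {
  expect_error(sim_config(n_patients = 10), "seed")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_patients = 0, seed = 1), "positive")
  expect_error(sim_config(n_patients = 10, seed = 1,
                          baseline_hazard = rep(0.001, 59)), "60")
  expect_error(sim_config(n_patients = 10, seed = 1,
                          arms = c("a", "a", "b", "c")), "distinct")
  expect_error(sim_config(n_patients = 10, seed = 1,
                          adverse_reaction_prob = 1.2), "\\[0, 1\\]")
})

test_that("null constant-hazard incidence matches the closed-form product", {
  # 1 - 0.999^60 with null arm effects and no covariate effects on hazard
  cfg <- sim_config(n_patients = 20000, seed = 42, baseline_hazard = 0.001,
                    hazard_terms = character(0),
                    hazard_coefficients = numeric(0),
                    noncv_death_hazard = 0, missingness_spec = list())
  tabs <- generate_cohort(cfg)
  tr <- attr(tabs, "truth")
  p_true <- 1 - 0.999^60
  for (a in study_drugs()) {
    sel <- tr$arm == a
    p_hat <- mean(!is.na(tr$mace_month[sel]))
    se <- sqrt(p_true * (1 - p_true) / sum(sel))
    expect_lt(abs(p_hat - p_true), 3 * se)
  }
})

test_that("true_marginal_risk matches closed forms and strata averages", {
  cfg <- sim_config(n_patients = 10, seed = 1, baseline_hazard = 0.01,
                    hazard_terms = character(0),
                    hazard_coefficients = numeric(0),
                    missingness_spec = list())
  pop <- data.frame(age = c(50, 60), diabetes = c(0L, 1L))
  expect_equal(true_marginal_risk(cfg, "olanzapine", pop, 60),
               1 - 0.99^60, tolerance = 1e-12)
  expect_identical(true_marginal_risk(cfg, "olanzapine", pop, 0), 0)
  expect_error(true_marginal_risk(cfg, "clozapine", pop), "unknown arm")

  # two strata with different hazards: stratum-weighted mean of closed forms
  cfg2 <- sim_config(n_patients = 10, seed = 1, baseline_hazard = 0.002,
                     hazard_terms = c(diabetes = "diabetes"),
                     hazard_coefficients = c(diabetes = 1),
                     missingness_spec = list())
  h0 <- 0.002
  h1 <- plogis(qlogis(0.002) + 1)
  manual <- mean(c(1 - (1 - h0)^60, 1 - (1 - h1)^60))
  expect_equal(true_marginal_risk(cfg2, "olanzapine", pop, 60), manual,
               tolerance = 1e-12)
  # with null arm effects the truth is identical across arms
  risks <- vapply(study_drugs(), function(a)
    true_marginal_risk(cfg2, a, pop, 60), numeric(1))
  expect_true(all(risks == risks[1]))
})

test_that("generation is byte-identical under a fixed seed and stable in n", {
  cfg <- sim_config(n_patients = 400, seed = 9)
  t1 <- generate_cohort(cfg)
  t2 <- generate_cohort(cfg)
  expect_identical(t1, t2)
  # enlarging the cohort never perturbs earlier patients' draws
  cfg_big <- sim_config(n_patients = 600, seed = 9)
  t3 <- generate_cohort(cfg_big)
  p_small <- t1$patients
  p_big <- t3$patients[t3$patients$patient_id <= 400, ]
  rownames(p_big) <- NULL
  expect_equal(p_small, p_big)
  tr1 <- attr(t1, "truth")
  tr3 <- attr(t3, "truth")[1:400, ]
  expect_equal(tr1$mace_month, tr3$mace_month)
})

test_that("missingness is MAR as configured and refuses outcome fields", {
  cfg <- sim_config(n_patients = 6000, seed = 3, missingness_spec = list(
    smoking = list(terms = character(0), coefficients = qlogis(0.2)),
    bmi = list(terms = c(male = "sex == 'male'"),
               coefficients = c(qlogis(0.10), 1))))
  tabs <- generate_cohort(cfg)
  masked <- apply_missingness(tabs, cfg)
  p <- masked$patients
  # constant 20% missingness: binomial oracle
  se <- sqrt(0.2 * 0.8 / nrow(p))
  expect_lt(abs(mean(is.na(p$smoking)) - 0.2), 3 * se)
  # BMI missingness differs by sex as specified (logistic oracle)
  p_f <- plogis(qlogis(0.10))
  p_m <- plogis(qlogis(0.10) + 1)
  for (sx in c("female", "male")) {
    sel <- p$sex == sx
    target <- if (sx == "male") p_m else p_f
    expect_lt(abs(mean(is.na(p$bmi[sel])) - target),
              3 * sqrt(target * (1 - target) / sum(sel)))
  }
  # complete copy retained
  expect_false(anyNA(attr(masked, "complete_patients")$smoking))
  # all-zero probabilities leave the tables unchanged
  cfg0 <- sim_config(n_patients = 500, seed = 3, missingness_spec = list(
    bmi = list(terms = character(0), coefficients = -Inf)))
  tabs0 <- generate_cohort(cfg0)
  expect_equal(apply_missingness(tabs0, cfg0)$patients, tabs0$patients)
  # outcome fields are never maskable
  expect_error(sim_config(n_patients = 10, seed = 1, missingness_spec = list(
    itt_event_month = list(terms = character(0), coefficients = 0))),
    "outcome")
})

test_that("scenario presets encode their stated conditions", {
  cfg <- scenario_config("protective", 100, seed = 1)
  expect_equal(unname(cfg$arm_log_hazard["aripiprazole"]), log(0.8))
  cfg2 <- scenario_config("rare_event", 100, seed = 1)
  expect_true(all(cfg2$baseline_hazard <= 0.005))
  expect_equal(unname(cfg2$arm_log_hazard["aripiprazole"]), log(0.6))
  cfg3 <- scenario_config("informative_censoring", 100, seed = 1)
  expect_true(all(cfg3$ps_coefficients[, -1] == 0))
})
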