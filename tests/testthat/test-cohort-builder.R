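# Eligibility, index dates, outcome derivation, per-protocol censoring, and
# dose conversion, checked against hand-walked fixtures and a day-level
# brute-force oracle.

test_that("olanzapine-equivalent doses follow the DDD table", {
  expect_equal(olanzapine_equivalent_dose("olanzapine", 10), 10)
  expect_equal(olanzapine_equivalent_dose("risperidone", 5), 10)
  expect_equal(olanzapine_equivalent_dose("aripiprazole", 30), 20)
  expect_equal(olanzapine_equivalent_dose("quetiapine", 400), 10)
  expect_error(olanzapine_equivalent_dose("clozapine", 10), "unknown drug")
  expect_error(olanzapine_equivalent_dose("olanzapine", -1), "positive")
})

test_that("one violation per patient yields one exclusion per criterion", {
  tabs <- empty_tables()
  tabs <- add_patient(tabs, 1, age = 39)                          # age
  tabs <- add_patient(tabs, 2, registration_days_before = 100)    # registration
  tabs <- add_patient(tabs, 3)                                    # LAI prior
  tabs <- add_rx(tabs, 3, as.Date("2010-06-01") - 30, lai = TRUE)
  tabs <- add_patient(tabs, 4, prn = TRUE)                        # pro re nata
  tabs <- add_patient(tabs, 5, linkage = FALSE)                   # linkage
  tabs <- add_patient(tabs, 6, smi_days_before = -40)             # SMI late
  cohort <- apply_eligibility(tabs)
  expect_equal(nrow(cohort), 0)
  flow <- attr(cohort, "flow")
  expect_equal(unname(flow["candidates"]), 6)
  for (r in c("age", "registration", "lai", "pro_re_nata", "linkage",
              "smi_timing")) {
    expect_equal(unname(flow[r]), 1)
  }
  # flow-diagram conservation
  excl <- setdiff(names(flow), c("candidates", "included"))
  expect_equal(sum(flow[excl]) + flow[["included"]], flow[["candidates"]])
})

test_that("SMI codes within the 30-day grace window qualify", {
  tabs <- add_patient(empty_tables(), 1, smi_days_before = -25)  # 25 d after
  expect_equal(nrow(apply_eligibility(tabs)), 1)
  tabs2 <- add_patient(empty_tables(), 1, smi_days_before = -31)
  expect_equal(nrow(apply_eligibility(tabs2)), 0)
  # ... unless the inclusive sensitivity variant is requested
  expect_equal(nrow(apply_eligibility(
    tabs2, eligibility_criteria(inclusive_smi = TRUE))), 1)
})

test_that("age bounds, prior history, and co-prescription exclude", {
  expect_equal(nrow(apply_eligibility(add_patient(empty_tables(), 1,
                                                  age = 100))), 0)
  expect_equal(nrow(apply_eligibility(add_patient(empty_tables(), 1,
                                                  age = 40))), 1)
  tabs <- add_episode(add_patient(empty_tables(), 1),
                      1, "2009-01-01", "I639")
  expect_equal(unname(attr(apply_eligibility(tabs),
                           "flow")["prior_history"]), 1)
  tabs2 <- add_rx(add_patient(empty_tables(), 1), 1, "2010-06-01",
                  drug = "quetiapine")
  expect_equal(unname(attr(apply_eligibility(tabs2),
                           "flow")["coprescription"]), 1)
})

test_that("an empty prescriptions table warns and returns an empty cohort", {
  expect_warning(cohort <- apply_eligibility(empty_tables()), "empty")
  expect_equal(nrow(cohort), 0)
})

test_that("outcome rules: components, 28-day fatality, censoring", {
  idx <- as.Date("2010-06-01")
  base <- add_patient(add_patient(add_patient(empty_tables(), 1), 2), 3)
  # MI admission in month 7
  tabs <- add_episode(base, 1, idx + round(6.5 * 30.4375), "I219")
  # stroke day 100, death (non-circulatory cause) day 120 -> CV death
  tabs <- add_episode(tabs, 2, idx + 100, "I639")
  tabs <- add_death(tabs, 2, idx + 120, "C809")
  # non-CV death month 30, no admissions
  tabs <- add_death(tabs, 3, idx + round(29.5 * 30.4375), "J189")
  cohort <- derive_outcomes(apply_eligibility(tabs), tabs$episodes,
                            tabs$deaths)
  p1 <- cohort[cohort$patient_id == 1, ]
  expect_equal(p1$itt_event_month, 7)
  expect_equal(p1$itt_event_type, "mi")
  p2 <- cohort[cohort$patient_id == 2, ]
  expect_equal(p2$itt_event_type, "cv_death")
  expect_equal(p2$itt_event_month, month_of_day(100))
  expect_true(is.na(p2$mi_event_month) && is.na(p2$stroke_event_month))
  expect_equal(p2$cv_death_event_month, month_of_day(100))
  p3 <- cohort[cohort$patient_id == 3, ]
  expect_true(is.na(p3$itt_event_month))
  expect_equal(p3$itt_censor_month, 30)
  expect_equal(p3$itt_censor_reason, "noncv_death")
})

test_that("a death more than 28 days after a stroke leaves it non-fatal", {
  idx <- as.Date("2010-06-01")
  tabs <- add_episode(add_patient(empty_tables(), 1), 1, idx + 100, "I639")
  tabs <- add_death(tabs, 1, idx + 140, "C809")
  cohort <- derive_outcomes(apply_eligibility(tabs), tabs$episodes,
                            tabs$deaths)
  expect_equal(cohort$itt_event_type, "stroke")
  expect_equal(cohort$stroke_event_month, month_of_day(100))
})

test_that("a MACE admission before index in the built cohort is rejected", {
  idx <- as.Date("2010-06-01")
  tabs <- add_patient(empty_tables(), 1)
  cohort <- apply_eligibility(tabs)
  eps <- data.frame(patient_id = 1, admission_date = idx - 50,
                    primary_icd10 = "I219")
  expect_error(derive_outcomes(cohort, eps, tabs$deaths), "prevalent")
})

test_that("per-protocol censoring reasons and the exemption rule", {
  idx <- as.Date("2010-06-01")
  # discontinuation: last prescription day 300 -> censor at day 483
  tabs <- add_rx(add_patient(empty_tables(), 1), 1, idx + 300)
  cohort <- derive_per_protocol(
    derive_outcomes(apply_eligibility(tabs), tabs$episodes, tabs$deaths),
    tabs$prescriptions, tabs$adverse_reaction_codes, tabs$patients)
  expect_equal(cohort$pp_censor_reason, "discontinuation")
  expect_equal(cohort$pp_censor_month, month_of_day(483))

  # switch at month 14 with an adverse-reaction code 10 days later: exempt
  tabs2 <- add_patient(empty_tables(), 1)
  for (m in 1:13) tabs2 <- add_rx(tabs2, 1, idx + round((m - 1) * 30.4375))
  sw_day <- round(13.5 * 30.4375)
  tabs2 <- add_rx(tabs2, 1, idx + sw_day, drug = "risperidone")
  tabs2$adverse_reaction_codes <- data.frame(
    patient_id = 1, date = idx + sw_day + 10, drug = "olanzapine")
  cohort2 <- derive_per_protocol(
    derive_outcomes(apply_eligibility(tabs2), tabs2$episodes, tabs2$deaths),
    tabs2$prescriptions, tabs2$adverse_reaction_codes, tabs2$patients)
  expect_true(is.na(cohort2$pp_censor_month))
  expect_true(cohort2$pp_exempted)
  # without the code the same history censors as an addition/switch
  cohort2b <- derive_per_protocol(
    derive_outcomes(apply_eligibility(tabs2), tabs2$episodes, tabs2$deaths),
    tabs2$prescriptions, NULL, tabs2$patients)
  expect_false(is.na(cohort2b$pp_censor_month))
  expect_false(cohort2b$pp_exempted)

  # continuous monthly prescriptions to month 60: never censored
  tabs3 <- add_patient(empty_tables(), 1)
  for (m in 1:60) tabs3 <- add_rx(tabs3, 1, idx + round((m - 1) * 30.4375))
  cohort3 <- derive_per_protocol(
    derive_outcomes(apply_eligibility(tabs3), tabs3$episodes, tabs3$deaths),
    tabs3$prescriptions, NULL, tabs3$patients)
  expect_true(is.na(cohort3$pp_censor_month))
})

test_that("per-protocol follow-up is nested in intention-to-treat follow-up", {
  cfg <- sim_config(n_patients = 1500, seed = 17, missingness_spec = list())
  tabs <- generate_cohort(cfg)
  cohort <- derive_per_protocol(
    derive_outcomes(apply_eligibility(tabs), tabs$episodes, tabs$deaths),
    tabs$prescriptions, tabs$adverse_reaction_codes, tabs$patients)
  term <- ifelse(is.na(cohort$itt_event_month), cohort$itt_censor_month,
                 cohort$itt_event_month)
  has_pp <- !is.na(cohort$pp_censor_month)
  expect_true(all(cohort$pp_censor_month[has_pp] <= term[has_pp]))
  expect_true(all(term >= 1 & term <= 60))
  # every patient appears once
  expect_false(any(duplicated(cohort$patient_id)))
})

test_that("eligibility is deterministic and idempotent on fixed tables", {
  cfg <- sim_config(n_patients = 500, seed = 23, missingness_spec = list())
  tabs <- generate_cohort(cfg)
  c1 <- apply_eligibility(tabs)
  c2 <- apply_eligibility(tabs)
  expect_identical(c1, c2)
})

test_that("month-level assignments agree with a day-level oracle", {
  cfg <- sim_config(n_patients = 300, seed = 29, missingness_spec = list())
  tabs <- generate_cohort(cfg)
  cohort <- derive_outcomes(apply_eligibility(tabs), tabs$episodes,
                            tabs$deaths)
  set.seed(4)
  sample_ids <- sample(cohort$patient_id, min(50, nrow(cohort)))
  for (pid in sample_ids) {
    row <- cohort[cohort$patient_id == pid, ]
    eps <- tabs$episodes[tabs$episodes$patient_id == pid, ]
    dth <- tabs$deaths[tabs$deaths$patient_id == pid, ]
    day <- function(d) as.numeric(d - row$index_date)
    # brute force: scan days 1..1826 for the first qualifying event
    ev_day <- Inf
    ev_type <- NA
    mi_s <- eps[grepl("^I21", eps$primary_icd10) & day(eps$admission_date) >= 1, ]
    st_s <- eps[grepl("^I6[0-4]", eps$primary_icd10) & day(eps$admission_date) >= 1, ]
    cand <- rbind(
      if (nrow(mi_s)) data.frame(d = day(mi_s$admission_date), type = "mi"),
      if (nrow(st_s)) data.frame(d = day(st_s$admission_date), type = "stroke"))
    if (!is.null(cand) && nrow(cand)) {
      cand <- cand[which.min(cand$d), ]
      ev_day <- cand$d
      ev_type <- cand$type
      if (nrow(dth) && day(dth$date[1]) - ev_day <= 28 &&
            day(dth$date[1]) >= ev_day) {
        ev_type <- "cv_death"
      }
    }
    if (nrow(dth) && grepl("^I", dth$underlying_cause_icd10[1]) &&
          day(dth$date[1]) < ev_day) {
      ev_day <- day(dth$date[1])
      ev_type <- "cv_death"
    }
    if (is.finite(ev_day) && ev_day <= 60 * 30.4375 &&
          month_of_day(ev_day) <= 60) {
      expect_equal(row$itt_event_month, month_of_day(ev_day), info = pid)
      expect_equal(row$itt_event_type, ev_type, info = pid)
    } else {
      expect_true(is.na(row$itt_event_month), info = pid)
    }
  }
})
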