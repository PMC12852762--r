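# Trial-emulation cohort construction: eligibility and index date, composite
# MACE outcome derivation under the intention-to-treat estimand, and
# per-protocol censoring.

.MI_RE <- "^I21"
.STROKE_RE <- "^I6[0-4]"
.HISTORY_RE <- "^I21|^I6[0-4]|^F0[0-3]|^G30"
.CV_CHAPTER_RE <- "^I"

#' Defined daily doses of the study antipsychotics
#'
#' WHO ATC defined daily doses (mg/day) used to express starting doses on a
#' common olanzapine-equivalent scale.
#'
#' @return Named numeric vector.
#' @export
ddd_table <- function() {
  c(aripiprazole = 15, olanzapine = 10, quetiapine = 400, risperidone = 5)
}

#' Olanzapine-equivalent daily dose
#'
#' Converts a daily dose of a study antipsychotic to olanzapine equivalents by
#' defined-daily-dose scaling: dose / DDD(drug) * DDD(olanzapine).
#'
#' @param drug Study drug label(s).
#' @param daily_dose_mg Daily dose(s) in mg (> 0).
#' @return Olanzapine-equivalent mg/day.
#' @export
olanzapine_equivalent_dose <- function(drug, daily_dose_mg) {
  ddd <- ddd_table()
  if (any(!drug %in% names(ddd))) {
    .stopf("unknown drug: %s",
           paste(setdiff(unique(drug), names(ddd)), collapse = ", "))
  }
  if (any(daily_dose_mg <= 0, na.rm = TRUE)) {
    .stopf("daily dose must be positive")
  }
  unname(daily_dose_mg / ddd[drug] * ddd["olanzapine"])
}

#' Eligibility criteria for the emulated trial
#'
#' @param age_range Inclusive age bounds at the index date.
#' @param registration_lookback_days Minimum continuous registration before
#'   index ("6 months", operationalised as 183 days).
#' @param recruitment_window Dates bounding eligible index prescriptions.
#' @param smi_grace_days_after_index SMI diagnoses recorded up to this many
#'   days after index still qualify (secondary-care communication delay).
#' @param lai_lookback_days Exclusion window for prior long-acting
#'   injectable antipsychotic prescriptions.
#' @param exclude_pro_re_nata Exclude index prescriptions labelled pro re nata.
#' @param require_linkage Require hospital/death linkage eligibility.
#' @param inclusive_smi Sensitivity variant: accept an SMI diagnosis recorded
#'   at any time (before or after index).
#' @return An object of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(age_range = c(40, 99),
                                 registration_lookback_days = 183,
                                 recruitment_window = as.Date(c("2005-01-01",
                                                                "2014-12-31")),
                                 smi_grace_days_after_index = 30,
                                 lai_lookback_days = 90,
                                 exclude_pro_re_nata = TRUE,
                                 require_linkage = TRUE,
                                 inclusive_smi = FALSE) {
  stopifnot(age_range[1] <= age_range[2],
            registration_lookback_days > 0,
            smi_grace_days_after_index >= 0, lai_lookback_days > 0,
            recruitment_window[1] <= recruitment_window[2])
  structure(list(age_range = age_range,
                 registration_lookback_days = registration_lookback_days,
                 recruitment_window = recruitment_window,
                 smi_grace_days_after_index = smi_grace_days_after_index,
                 lai_lookback_days = lai_lookback_days,
                 exclude_pro_re_nata = exclude_pro_re_nata,
                 require_linkage = require_linkage,
                 inclusive_smi = inclusive_smi),
            class = "eligibility_criteria")
}

#' Apply trial eligibility and set the index date
#'
#' The index date is the first (oral, non-injectable) study-drug prescription;
#' candidates are patients whose index falls inside the recruitment window.
#' Sequential exclusions: age outside range at index, registration shorter
#' than the lookback, prior stroke/MI/dementia, another antipsychotic
#' co-prescribed at index, a long-acting injectable in the prior window, a
#' pro re nata index prescription, linkage-ineligibility, and missing or
#' late SMI diagnosis. Per-criterion exclusion counts are attached as
#' `attr(, "flow")` (flow-diagram conservation: candidates = included + sum
#' of exclusions).
#'
#' @param tables A `mace_raw_tables` object (or an equivalently named list of
#'   data frames).
#' @param criteria An [eligibility_criteria()] object.
#' @return A cohort data frame (one row per eligible patient) holding the
#'   index date, arm, and baseline covariates; follow-up columns unfilled.
#' @export
apply_eligibility <- function(tables, criteria = eligibility_criteria()) {
  rx <- tables$prescriptions
  pats <- tables$patients
  eps <- tables$episodes
  if (is.null(rx) || nrow(rx) == 0) {
    warning("empty prescriptions table: returning empty cohort")
    cohort <- pats[0, c("patient_id"), drop = FALSE]
    attr(cohort, "flow") <- c(candidates = 0L, included = 0L)
    return(cohort)
  }
  rx <- rx[rx$drug %in% study_drugs(), , drop = FALSE]
  oral <- rx[!rx$long_acting_injectable, , drop = FALSE]
  oral <- oral[order(oral$patient_id, oral$date), , drop = FALSE]
  first <- oral[!duplicated(oral$patient_id), , drop = FALSE]

  idx <- data.frame(patient_id = first$patient_id,
                    index_date = first$date,
                    arm = first$drug,
                    index_dose_mg = first$daily_dose_mg,
                    index_prn = first$pro_re_nata,
                    stringsAsFactors = FALSE)
  # Co-prescription of a different study antipsychotic on the index date.
  im <- match(oral$patient_id, idx$patient_id)
  at_index <- oral$date == idx$index_date[im]
  sub <- oral[at_index, c("patient_id", "drug")]
  sub <- sub[!duplicated(sub), , drop = FALSE]
  multi <- table(sub$patient_id) > 1L
  idx$coprescribed <- idx$patient_id %in%
    as.integer(names(multi)[multi])
  # LAI in the prior lookback window.
  lai <- rx[rx$long_acting_injectable, , drop = FALSE]
  if (nrow(lai)) {
    lidx <- match(lai$patient_id, idx$patient_id)
    gap <- as.numeric(idx$index_date[lidx] - lai$date)
    hit <- unique(lai$patient_id[!is.na(gap) & gap > 0 &
                                   gap <= criteria$lai_lookback_days])
    idx$lai_prior <- idx$patient_id %in% hit
  } else idx$lai_prior <- FALSE
  # Prior MI/stroke/dementia from pre-index admissions or the history flag.
  if (!is.null(eps) && nrow(eps)) {
    eidx <- match(eps$patient_id, idx$patient_id)
    pre <- !is.na(eidx) &
      as.numeric(eps$admission_date - idx$index_date[eidx]) < 0 &
      grepl(.HISTORY_RE, eps$primary_icd10)
    idx$prior_history_ep <- idx$patient_id %in% unique(eps$patient_id[pre])
  } else idx$prior_history_ep <- FALSE

  m <- match(idx$patient_id, pats$patient_id)
  if (anyNA(m)) .stopf("prescriptions reference unknown patient ids")
  p <- pats[m, , drop = FALSE]
  idx$age <- as.integer(format(idx$index_date, "%Y")) - p$birth_year
  flow <- c(candidates = nrow(idx))
  keep <- rep(TRUE, nrow(idx))
  tally <- function(keep, bad, reason, flow) {
    drop <- keep & bad
    flow[reason] <- sum(drop)
    list(keep = keep & !bad, flow = flow)
  }
  st <- tally(keep, idx$index_date < criteria$recruitment_window[1] |
                idx$index_date > criteria$recruitment_window[2],
              "outside_window", flow)
  st <- tally(st$keep, idx$age < criteria$age_range[1] |
                idx$age > criteria$age_range[2], "age", st$flow)
  st <- tally(st$keep, as.numeric(idx$index_date - p$registration_date) <
                criteria$registration_lookback_days, "registration", st$flow)
  hist_flag <- idx$prior_history_ep |
    (if ("history_cvd_dementia" %in% names(p)) p$history_cvd_dementia else FALSE)
  st <- tally(st$keep, hist_flag, "prior_history", st$flow)
  st <- tally(st$keep, idx$coprescribed, "coprescription", st$flow)
  st <- tally(st$keep, idx$lai_prior, "lai", st$flow)
  if (criteria$exclude_pro_re_nata) {
    st <- tally(st$keep, idx$index_prn, "pro_re_nata", st$flow)
  }
  if (criteria$require_linkage) {
    st <- tally(st$keep, !p$practice_linkage_eligible, "linkage", st$flow)
  }
  smi_ok <- if (criteria$inclusive_smi) {
    !is.na(p$smi_diagnosis_date)
  } else {
    !is.na(p$smi_diagnosis_date) &
      as.numeric(p$smi_diagnosis_date - idx$index_date) <=
        criteria$smi_grace_days_after_index
  }
  st <- tally(st$keep, !smi_ok, "smi_timing", st$flow)
  keep <- st$keep
  flow <- c(st$flow, included = sum(keep))

  cohort <- data.frame(
    patient_id = idx$patient_id,
    index_date = idx$index_date,
    arm = factor(idx$arm, levels = study_drugs()),
    age = idx$age,
    sex = p$sex, ethnicity = p$ethnicity,
    smi_diagnosis = p$smi_diagnosis_type,
    imd_quintile = p$imd_quintile,
    diabetes = p$diabetes, hypertension = p$hypertension,
    smoking = p$smoking, bmi = p$bmi,
    prior_antipsychotic = p$prior_antipsychotic,
    starting_dose = olanzapine_equivalent_dose(idx$arm, idx$index_dose_mg),
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(cohort) <- NULL
  for (v in c("sex", "ethnicity", "smi_diagnosis", "imd_quintile",
              "smoking")) {
    if (!is.factor(cohort[[v]])) cohort[[v]] <- factor(cohort[[v]])
  }
  attr(cohort, "flow") <- flow
  attr(cohort, "criteria") <- criteria
  class(cohort) <- c("mace_cohort", "data.frame")
  cohort
}

#' Baseline covariate names of the default schema
#' @return Character vector of covariate column names.
#' @export
covariate_names <- function() {
  c("age", "sex", "ethnicity", "smi_diagnosis", "imd_quintile", "diabetes",
    "hypertension", "smoking", "bmi", "prior_antipsychotic", "starting_dose")
}

#' Derive intention-to-treat outcomes over the 60-month horizon
#'
#' The composite MACE is the first of: hospitalisation with primary ICD-10
#' I21* (MI) or I60*-I64* (stroke), or death registered with an underlying
#' cause in the circulatory-system chapter. A death from any cause within 28
#' days of an MI/stroke admission reclassifies that event as cardiovascular
#' death (timed at the admission). Follow-up is censored at the earliest of
#' non-cardiovascular death or 60 months. Component-specific event months are
#' also derived, with fatal MI/stroke counting as cardiovascular death and
#' not as the non-fatal component, so component analyses censor at component
#' rather than composite incidence.
#'
#' @param cohort An eligibility-built cohort.
#' @param episodes,deaths Raw hospital-admission and death tables.
#' @param horizon Months of follow-up (default 60).
#' @return The cohort with ITT follow-up columns: `itt_event_month`,
#'   `itt_event_type`, `itt_censor_month`, `itt_censor_reason`,
#'   `itt_terminal_day`, per-component event months, and death bookkeeping.
#' @export
derive_outcomes <- function(cohort, episodes, deaths,
                            horizon = HORIZON_MONTHS) {
  n <- nrow(cohort)
  horizon_days <- horizon * DAYS_PER_MONTH
  mi_day <- stroke_day <- rep(NA_real_, n)
  if (!is.null(episodes) && nrow(episodes)) {
    m <- match(episodes$patient_id, cohort$patient_id)
    day <- as.numeric(episodes$admission_date - cohort$index_date[m])
    is_mi <- grepl(.MI_RE, episodes$primary_icd10)
    is_st <- grepl(.STROKE_RE, episodes$primary_icd10)
    post <- !is.na(m) & day >= 1 & day <= horizon_days
    if (any(!is.na(m) & day < 0 & (is_mi | is_st))) {
      .stopf("MACE admission before index for an included patient: %s",
             "prevalent event leaked through eligibility")
    }
    agg_min <- function(sel) {
      if (!any(sel)) return(rep(NA_real_, n))
      tb <- tapply(day[sel], m[sel], min)
      out <- rep(NA_real_, n)
      out[as.integer(names(tb))] <- tb
      out
    }
    mi_day <- agg_min(post & is_mi)
    stroke_day <- agg_min(post & is_st)
  }
  death_day <- rep(NA_real_, n)
  death_cv <- rep(FALSE, n)
  if (!is.null(deaths) && nrow(deaths)) {
    dm <- match(deaths$patient_id, cohort$patient_id)
    sel <- !is.na(dm)
    first_death <- deaths[sel, , drop = FALSE][!duplicated(dm[sel]), , drop = FALSE]
    fm <- match(cohort$patient_id, first_death$patient_id)
    death_day <- as.numeric(first_death$date[fm] - cohort$index_date)
    death_cv <- !is.na(fm) &
      grepl(.CV_CHAPTER_RE, first_death$underlying_cause_icd10[fm])
  }

  # 28-day fatality reclassification (event timed at the admission).
  first_ep_day <- pmin(mi_day, stroke_day, na.rm = TRUE)
  first_ep_day[is.na(mi_day) & is.na(stroke_day)] <- NA
  fatal28 <- !is.na(first_ep_day) & !is.na(death_day) &
    death_day - first_ep_day >= 0 & death_day - first_ep_day <= 28
  ep_is_mi <- !is.na(first_ep_day) & !is.na(mi_day) & mi_day == first_ep_day

  # Component event days: fatal admissions count as cardiovascular death.
  mi_nf_day <- ifelse(fatal28 & ep_is_mi, NA, mi_day)
  stroke_nf_day <- ifelse(fatal28 & !ep_is_mi, NA, stroke_day)
  cvd_day <- ifelse(fatal28, first_ep_day,
                    ifelse(death_cv & !is.na(death_day) &
                             death_day <= horizon_days, death_day, NA))

  comp_day <- pmin(mi_nf_day, stroke_nf_day, cvd_day, na.rm = TRUE)
  comp_day[is.na(mi_nf_day) & is.na(stroke_nf_day) & is.na(cvd_day)] <- NA
  comp_type <- rep(NA_character_, n)
  comp_type[!is.na(comp_day) & !is.na(cvd_day) & comp_day == cvd_day] <- "cv_death"
  comp_type[is.na(comp_type) & !is.na(comp_day) & !is.na(mi_nf_day) &
              comp_day == mi_nf_day] <- "mi"
  comp_type[is.na(comp_type) & !is.na(comp_day)] <- "stroke"

  to_month <- function(day) {
    m <- month_of_day(day)
    m[!is.na(m) & m > horizon] <- NA
    m
  }
  ev_month <- to_month(comp_day)
  death_month <- to_month(death_day)
  noncv_death_month <- ifelse(!death_cv & !fatal28, death_month, NA_integer_)

  cohort$itt_event_month <- ev_month
  cohort$itt_event_type <- ifelse(is.na(ev_month), NA, comp_type)
  cohort$itt_event_day <- ifelse(is.na(ev_month), NA, comp_day)
  has_event <- !is.na(ev_month)
  # Event-first resolution: an event recorded in a month precedes that
  # month's censoring.
  cens_month <- ifelse(!is.na(noncv_death_month), noncv_death_month, horizon)
  cohort$itt_censor_month <- ifelse(has_event, NA_integer_,
                                    pmin(cens_month, horizon))
  cohort$itt_censor_reason <- ifelse(has_event, NA_character_,
                                     ifelse(!is.na(noncv_death_month) &
                                              noncv_death_month <= horizon,
                                            "noncv_death", "horizon"))
  cohort$itt_terminal_day <- ifelse(
    has_event, comp_day,
    ifelse(cohort$itt_censor_reason == "noncv_death", death_day, horizon_days))
  cohort$mi_event_month <- to_month(mi_nf_day)
  cohort$stroke_event_month <- to_month(stroke_nf_day)
  cohort$cv_death_event_month <- to_month(cvd_day)
  cohort$death_month <- death_month
  cohort$death_day <- death_day
  attr(cohort, "horizon") <- horizon
  cohort
}

#' Derive per-protocol censoring
#'
#' Per-protocol follow-up is censored at the earliest of: switch to another
#' study antipsychotic, addition of another study antipsychotic,
#' discontinuation (a configurable gap, default 183 days, after the last
#' prescription of the initiated drug), deregistration from primary care, or
#' the practice's last data-collection date. A new-drug prescription issued
#' while the original drug is still active (within the gap of its last issue)
#' is an addition, afterwards a switch. No censoring is applied when an
#' adverse-reaction code for the original drug is recorded within 30 days of
#' the strategy change (continuing under the original strategy is then
#' protocol-consistent); administrative censoring is never exempted.
#'
#' @param cohort Cohort with ITT follow-up derived.
#' @param prescriptions,adverse_reaction_codes Raw tables.
#' @param patients Optional patients table supplying deregistration and
#'   last-collection dates.
#' @param discontinuation_gap_days Days without a prescription that define
#'   discontinuation (and the "active" window for the switch/addition label).
#' @return The cohort with `pp_censor_month`, `pp_censor_reason`,
#'   `pp_censor_day`, and `pp_exempted` columns.
#' @export
derive_per_protocol <- function(cohort, prescriptions,
                                adverse_reaction_codes = NULL,
                                patients = NULL,
                                discontinuation_gap_days = 183) {
  n <- nrow(cohort)
  horizon <- attr(cohort, "horizon") %||% HORIZON_MONTHS
  horizon_days <- horizon * DAYS_PER_MONTH
  rx <- prescriptions[prescriptions$drug %in% study_drugs() &
                        !prescriptions$long_acting_injectable, , drop = FALSE]
  m <- match(rx$patient_id, cohort$patient_id)
  keep <- !is.na(m)
  rx <- rx[keep, , drop = FALSE]
  ridx <- m[keep]
  rx_day <- as.numeric(rx$date - cohort$index_date[ridx])
  own <- rx$drug == as.character(cohort$arm)[ridx]

  term_month <- ifelse(is.na(cohort$itt_event_month),
                       cohort$itt_censor_month, cohort$itt_event_month)
  term_day_i <- cohort$itt_terminal_day

  split_days <- function(sel) split(rx_day[sel], ridx[sel])
  own_days <- split_days(own & rx_day >= 0)
  oth_sel <- !own & rx_day >= 1
  oth_days <- split_days(oth_sel)

  adr_days <- list()
  if (!is.null(adverse_reaction_codes) && nrow(adverse_reaction_codes)) {
    am <- match(adverse_reaction_codes$patient_id, cohort$patient_id)
    ak <- !is.na(am) &
      adverse_reaction_codes$drug == as.character(cohort$arm)[am]
    adr_days <- split(
      as.numeric(adverse_reaction_codes$date[ak] -
                   cohort$index_date[am[ak]]), am[ak])
  }
  dereg_day <- lastc_day <- rep(NA_real_, n)
  if (!is.null(patients)) {
    pm <- match(cohort$patient_id, patients$patient_id)
    if ("deregistration_date" %in% names(patients)) {
      dereg_day <- as.numeric(patients$deregistration_date[pm] -
                                cohort$index_date)
    }
    if ("last_collection_date" %in% names(patients)) {
      lastc_day <- as.numeric(patients$last_collection_date[pm] -
                                cohort$index_date)
    }
  }

  pp_day <- rep(NA_real_, n)
  pp_reason <- rep(NA_character_, n)
  pp_exempt <- rep(FALSE, n)
  gap <- discontinuation_gap_days
  for (i in seq_len(n)) {
    od <- sort(own_days[[as.character(i)]] %||% numeric(0))
    if (!length(od)) next
    term_d <- min(term_day_i[i], horizon_days)
    cand_day <- numeric(0); cand_reason <- character(0); cand_anchor <- numeric(0)
    oth <- oth_days[[as.character(i)]]
    if (!is.null(oth)) {
      d1 <- min(oth)
      prev <- od[od <= d1]
      reason <- if (length(prev) && d1 - max(prev) <= gap) "addition" else "switch"
      cand_day <- c(cand_day, d1)
      cand_reason <- c(cand_reason, reason)
      cand_anchor <- c(cand_anchor, d1)
    }
    last_own <- max(od)
    if (last_own + gap < term_d) {
      cand_day <- c(cand_day, last_own + gap)
      cand_reason <- c(cand_reason, "discontinuation")
      cand_anchor <- c(cand_anchor, last_own)
    }
    if (!is.na(dereg_day[i])) {
      cand_day <- c(cand_day, dereg_day[i])
      cand_reason <- c(cand_reason, "deregistration")
      cand_anchor <- c(cand_anchor, NA)
    }
    if (!is.na(lastc_day[i])) {
      cand_day <- c(cand_day, lastc_day[i])
      cand_reason <- c(cand_reason, "last_collection")
      cand_anchor <- c(cand_anchor, NA)
    }
    if (!length(cand_day)) next
    o <- order(cand_day)
    ad <- adr_days[[as.character(i)]] %||% numeric(0)
    for (j in o) {
      strategy <- cand_reason[j] %in% c("switch", "addition", "discontinuation")
      if (strategy && length(ad) &&
          any(ad >= cand_anchor[j] & ad <= cand_anchor[j] + 30)) {
        # Adverse-reaction exemption: the change is strategy-consistent, so
        # neither this deviation nor its downstream consequences censor.
        pp_exempt[i] <- TRUE
        break
      }
      pp_day[i] <- cand_day[j]
      pp_reason[i] <- cand_reason[j]
      break
    }
  }
  pp_month <- month_of_day(pp_day)
  beyond <- !is.na(pp_month) & pp_month > term_month
  pp_month[beyond] <- NA
  pp_reason[beyond] <- NA
  pp_day[beyond] <- NA
  cohort$pp_censor_month <- pp_month
  cohort$pp_censor_day <- pp_day
  cohort$pp_censor_reason <- pp_reason
  cohort$pp_exempted <- pp_exempt
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a
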