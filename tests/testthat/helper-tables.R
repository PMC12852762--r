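# Hand-built raw-table fixtures for cohort-construction tests.

empty_tables <- function() {
  structure(list(
    patients = data.frame(
      patient_id = integer(0), birth_year = integer(0),
      sex = character(0), ethnicity = character(0),
      imd_quintile = character(0),
      registration_date = as.Date(character(0)),
      practice_linkage_eligible = logical(0),
      smi_diagnosis_date = as.Date(character(0)),
      smi_diagnosis_type = character(0),
      diabetes = integer(0), hypertension = integer(0),
      smoking = character(0), bmi = numeric(0),
      prior_antipsychotic = integer(0),
      history_cvd_dementia = logical(0),
      deregistration_date = as.Date(character(0)),
      last_collection_date = as.Date(character(0))),
    prescriptions = data.frame(
      patient_id = integer(0), date = as.Date(character(0)),
      drug = character(0), daily_dose_mg = numeric(0),
      pro_re_nata = logical(0), long_acting_injectable = logical(0)),
    episodes = data.frame(patient_id = integer(0),
                          admission_date = as.Date(character(0)),
                          primary_icd10 = character(0)),
    deaths = data.frame(patient_id = integer(0),
                        date = as.Date(character(0)),
                        underlying_cause_icd10 = character(0)),
    adverse_reaction_codes = data.frame(patient_id = integer(0),
                                        date = as.Date(character(0)),
                                        drug = character(0))),
    class = "mace_raw_tables")
}

# One fully eligible patient (index 2010-06-01, olanzapine 10 mg) plus any
# overrides; returns the patients row and matching index prescription.
add_patient <- function(tables, id, index = as.Date("2010-06-01"),
                        drug = "olanzapine", dose = 10, age = 55,
                        registration_days_before = 400,
                        smi_days_before = 200, linkage = TRUE,
                        prn = FALSE, history = FALSE) {
  tables$patients <- rbind(tables$patients, data.frame(
    patient_id = id, birth_year = as.integer(format(index, "%Y")) - age,
    sex = "female", ethnicity = "white", imd_quintile = "3",
    registration_date = index - registration_days_before,
    practice_linkage_eligible = linkage,
    smi_diagnosis_date = index - smi_days_before,
    smi_diagnosis_type = "schizophrenia",
    diabetes = 0L, hypertension = 0L, smoking = "never", bmi = 25,
    prior_antipsychotic = 0L, history_cvd_dementia = history,
    deregistration_date = as.Date(NA),
    last_collection_date = as.Date("2019-12-31")))
  tables$prescriptions <- rbind(tables$prescriptions, data.frame(
    patient_id = id, date = index, drug = drug, daily_dose_mg = dose,
    pro_re_nata = prn, long_acting_injectable = FALSE))
  tables
}

add_rx <- function(tables, id, date, drug = "olanzapine", dose = 10,
                   prn = FALSE, lai = FALSE) {
  tables$prescriptions <- rbind(tables$prescriptions, data.frame(
    patient_id = id, date = as.Date(date), drug = drug, daily_dose_mg = dose,
    pro_re_nata = prn, long_acting_injectable = lai))
  tables
}

add_episode <- function(tables, id, date, code) {
  tables$episodes <- rbind(tables$episodes, data.frame(
    patient_id = id, admission_date = as.Date(date), primary_icd10 = code))
  tables
}

add_death <- function(tables, id, date, cause) {
  tables$deaths <- rbind(tables$deaths, data.frame(
    patient_id = id, date = as.Date(date), underlying_cause_icd10 = cause))
  tables
}
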