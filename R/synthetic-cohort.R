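# Synthetic linked-EHR cohort generator.
#
# Emulates the structure of linked UK primary-care (prescriptions, patient
# registration), hospital-admission (episodes with ICD-10 primary diagnoses),
# and death-registration tables, with known ground-truth treatment effects,
# confounded multinomial treatment assignment, a monthly discrete-time MACE
# hazard, competing non-cardiovascular death, adherence (switch / addition /
# discontinuation) processes, rare adverse-reaction codes, and
# missing-at-random covariate masking.

#' Default baseline covariate specification
#'
#' An eleven-variable core covariate set: age, sex, ethnicity, SMI diagnosis,
#' deprivation quintile, diabetes, hypertension, smoking status, body mass
#' index, prior antipsychotic use, and starting daily dose (olanzapine
#' equivalents). Marginal distributions are chosen to resemble a UK severe
#' mental illness cohort aged 40-99.
#'
#' @return A list of per-covariate specifications (name, kind, distribution
#'   parameters) consumed by [sim_config()].
#' @export
default_covariate_spec <- function() {
  list(
    list(name = "age", kind = "continuous", dist = "gamma_shift",
         shift = 40, shape = 1.8, scale = 8, max = 99),
    list(name = "sex", kind = "categorical",
         levels = c("female", "male"), probs = c(0.57, 0.43)),
    list(name = "ethnicity", kind = "categorical",
         levels = c("white", "asian", "black", "mixed_other"),
         probs = c(0.846, 0.065, 0.066, 0.023)),
    list(name = "smi_diagnosis", kind = "categorical",
         levels = c("bipolar_disorder", "other_psychoses", "schizophrenia"),
         probs = c(0.413, 0.390, 0.197)),
    list(name = "imd_quintile", kind = "categorical",
         levels = as.character(1:5),
         probs = c(0.130, 0.155, 0.190, 0.235, 0.290)),
    list(name = "diabetes", kind = "binary", prob = 0.14),
    list(name = "hypertension", kind = "binary", prob = 0.28),
    list(name = "smoking", kind = "categorical",
         levels = c("never", "ex", "current"), probs = c(0.397, 0.148, 0.455)),
    list(name = "bmi", kind = "continuous", dist = "normal",
         mean = 28, sd = 6, min = 15, max = 55),
    list(name = "prior_antipsychotic", kind = "binary", prob = 0.26),
    list(name = "starting_dose", kind = "continuous", dist = "lognormal",
         meanlog = log(5.5), sdlog = 0.5, max = 40)
  )
}

# Centred/scaled design terms shared by the default treatment-assignment and
# hazard models (evaluated against the covariate frame).
.default_ps_terms <- function() {
  c(age10   = "(age - 55) / 10",
    male    = "sex == 'male'",
    diabetes = "diabetes",
    smoker  = "smoking == 'current'",
    bmi6    = "(bmi - 28) / 6",
    schizo  = "smi_diagnosis == 'schizophrenia'",
    dose4   = "(starting_dose - 6.5) / 4",
    prior_ap = "prior_antipsychotic")
}

.default_ps_coefficients <- function() {
  terms <- c("(intercept)", names(.default_ps_terms()))
  m <- matrix(0, nrow = 4, ncol = length(terms),
              dimnames = list(study_drugs(), terms))
  # Channelling: comparators attract older patients (strongest for
  # risperidone); aripiprazole attracts diabetes and higher BMI.
  m["olanzapine", ]  <- c(1.48, 0.10, 0.00, -0.50, 0.10, -0.30,  0.20,  0.10, 0.00)
  m["quetiapine", ]  <- c(1.13, 0.45, 0.05, -0.40, 0.00, -0.25, -0.20, -0.20, 0.05)
  m["risperidone", ] <- c(1.02, 0.75, 0.10, -0.45, 0.00, -0.30,  0.10, -0.10, 0.10)
  m
}

.default_hazard_terms <- function() {
  c(age10   = "(age - 55) / 10",
    male    = "sex == 'male'",
    diabetes = "diabetes",
    smoker  = "smoking == 'current'",
    hypertension = "hypertension",
    bmi6    = "(bmi - 28) / 6")
}

.default_hazard_coefficients <- function() {
  c(age10 = 0.70, male = 0.30, diabetes = 0.60, smoker = 0.50,
    hypertension = 0.30, bmi6 = 0.15)
}

.default_missingness_spec <- function() {
  list(
    ethnicity = list(terms = character(0), coefficients = -2.64),
    imd_quintile = list(terms = character(0), coefficients = -3.17),
    smoking = list(terms = c(age10 = "(2010 - birth_year - 55) / 10"),
                   coefficients = c(-1.90, -0.15)),
    bmi = list(terms = c(male = "sex == 'male'"),
               coefficients = c(-1.30, -0.25)),
    starting_dose = list(terms = character(0), coefficients = -2.90)
  )
}

#' Build a simulation configuration
#'
#' Defines the full data-generating process for the synthetic linked cohort:
#' covariate distributions, confounded multinomial treatment assignment,
#' monthly MACE hazards, competing non-cardiovascular death, adherence, rare
#' adverse-reaction coding, eligibility-violation rates, and MAR covariate
#' missingness. Defaults emulate the observed conditions of a UK severe
#' mental illness cohort: a ~5.8% five-year MACE risk, ~10% five-year
#' non-cardiovascular mortality, and 38-45% non-adherence by five years.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Master seed (required; each table draws from an independent
#'   substream so regeneration is byte-identical and enlarging the cohort
#'   never perturbs earlier patients).
#' @param arms Ordered treatment labels; exactly four distinct strategies,
#'   the first being the reference.
#' @param covariate_spec Covariate distribution list, see
#'   [default_covariate_spec()].
#' @param ps_terms Named character vector of design expressions for the
#'   treatment-assignment (softmax) model.
#' @param ps_coefficients arms x (intercept + terms) coefficient matrix on the
#'   softmax scale; the reference-arm row should be zero.
#' @param baseline_hazard Monthly baseline MACE probability schedule h0(t),
#'   length 60 (or a scalar, recycled).
#' @param arm_log_hazard Named per-arm additive terms on the logit monthly
#'   hazard (zero = no treatment effect).
#' @param hazard_terms,hazard_coefficients Covariate design and additive
#'   log-odds effects on the monthly MACE hazard.
#' @param noncv_death_hazard Monthly probability of non-cardiovascular death
#'   (scalar or length 60).
#' @param adherence List with `monthly_deviation` (named per-arm monthly
#'   probability of abandoning the initiated strategy), `split` (named
#'   probabilities over switch / addition / discontinuation), and optional
#'   `terms` / `coefficients` giving additive covariate effects on the logit
#'   monthly deviation probability.
#' @param adverse_reaction_prob Probability that a strategy deviation carries
#'   a recorded adverse-reaction code for the original drug within 30 days.
#' @param event_type_probs Named probabilities that a MACE is a myocardial
#'   infarction, stroke, or (direct) cardiovascular death.
#' @param fatal_28day_prob Probability that an MI/stroke admission is followed
#'   by death within 28 days (and is therefore coded cardiovascular death).
#' @param comorbidity_onset_prob Monthly probability of a new comorbidity
#'   admission (feeds the time-varying censoring-weight models).
#' @param eligibility_violations Named rates of patients seeded with one
#'   eligibility violation each (late SMI coding, missing SMI code, pro re
#'   nata first prescription, prior long-acting injectable, short
#'   registration, linkage-ineligibility, prior CVD/dementia, age under 40,
#'   co-prescription at index, deregistration during follow-up).
#' @param missingness_spec Per-covariate MAR logistic models (named list of
#'   `terms` and `coefficients` on fully observed fields).
#' @param recruitment_window Dates bounding first prescriptions.
#' @return An object of class `mace_sim_config`.
#' @export
sim_config <- function(n_patients = 20000,
                       seed,
                       arms = study_drugs(),
                       covariate_spec = default_covariate_spec(),
                       ps_terms = .default_ps_terms(),
                       ps_coefficients = .default_ps_coefficients(),
                       baseline_hazard = 4.2e-4,
                       arm_log_hazard = stats::setNames(rep(0, 4), study_drugs()),
                       hazard_terms = .default_hazard_terms(),
                       hazard_coefficients = .default_hazard_coefficients(),
                       noncv_death_hazard = 0.0018,
                       adherence = list(
                         monthly_deviation = c(aripiprazole = 0.01002,
                                               olanzapine   = 0.00965,
                                               quetiapine   = 0.00802,
                                               risperidone  = 0.00908),
                         split = c(switch = 0.3, addition = 0.2,
                                   discontinuation = 0.5),
                         terms = NULL, coefficients = NULL),
                       adverse_reaction_prob = 0.01,
                       event_type_probs = c(mi = 0.35, stroke = 0.40,
                                            cv_death = 0.25),
                       fatal_28day_prob = 0.15,
                       comorbidity_onset_prob = 0.008,
                       eligibility_violations = c(
                         late_smi = 0.03, no_smi = 0.01, prn_first = 0.02,
                         lai_prior = 0.01, short_registration = 0.02,
                         not_linkage = 0.02, prior_cvd_dementia = 0.03,
                         underage = 0.01, coprescribed = 0.01,
                         deregistration = 0.02),
                       missingness_spec = .default_missingness_spec(),
                       recruitment_window = as.Date(c("2005-01-01",
                                                      "2014-12-31"))) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    .stopf("a master seed is required (reproducibility contract)")
  }
  if (length(baseline_hazard) == 1L) {
    baseline_hazard <- rep(baseline_hazard, HORIZON_MONTHS)
  }
  if (length(noncv_death_hazard) == 1L) {
    noncv_death_hazard <- rep(noncv_death_hazard, HORIZON_MONTHS)
  }
  cfg <- structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    arms = arms, covariate_spec = covariate_spec,
    ps_terms = ps_terms, ps_coefficients = ps_coefficients,
    baseline_hazard = baseline_hazard, arm_log_hazard = arm_log_hazard,
    hazard_terms = hazard_terms, hazard_coefficients = hazard_coefficients,
    noncv_death_hazard = noncv_death_hazard, adherence = adherence,
    adverse_reaction_prob = adverse_reaction_prob,
    event_type_probs = event_type_probs, fatal_28day_prob = fatal_28day_prob,
    comorbidity_onset_prob = comorbidity_onset_prob,
    eligibility_violations = eligibility_violations,
    missingness_spec = missingness_spec,
    recruitment_window = recruitment_window), class = "mace_sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config Object to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "mace_sim_config"))
  if (config$n_patients <= 0) .stopf("n_patients must be positive")
  if (length(unique(config$arms)) != 4L) {
    .stopf("arms must hold exactly 4 distinct labels")
  }
  for (h in list(config$baseline_hazard, config$noncv_death_hazard)) {
    if (length(h) != HORIZON_MONTHS) {
      .stopf("hazard schedules must have exactly %d entries", HORIZON_MONTHS)
    }
    if (any(h < 0 | h > 1)) .stopf("hazard probabilities must lie in [0, 1]")
  }
  probs <- c(config$adherence$monthly_deviation, config$adherence$split,
             config$adverse_reaction_prob, config$event_type_probs,
             config$fatal_28day_prob, config$comorbidity_onset_prob,
             config$eligibility_violations)
  if (any(probs < 0 | probs > 1)) {
    .stopf("all probability parameters must lie in [0, 1]")
  }
  if (!setequal(rownames(config$ps_coefficients), config$arms)) {
    .stopf("ps_coefficients rows must be named by the arms")
  }
  outcome_fields <- c("arm", "itt_event_month", "itt_event_type",
                      "itt_censor_month", "death_month")
  bad <- intersect(names(config$missingness_spec), outcome_fields)
  if (length(bad)) {
    .stopf("missingness_spec must not name treatment/outcome fields: %s",
           paste(bad, collapse = ", "))
  }
  invisible(config)
}

# Draw the baseline covariate frame (one independent substream per variable).
.draw_covariates <- function(config) {
  n <- config$n_patients
  seed <- config$seed
  out <- list()
  for (spec in config$covariate_spec) {
    v <- .substream(seed, paste0("covariate:", spec$name), {
      switch(spec$kind,
        binary = as.integer(stats::runif(n) < spec$prob),
        categorical = {
          u <- stats::runif(n)
          idx <- findInterval(u, cumsum(spec$probs[-length(spec$probs)])) + 1L
          factor(spec$levels[idx], levels = spec$levels)
        },
        continuous = {
          x <- switch(spec$dist,
            gamma_shift = spec$shift + stats::rgamma(n, shape = spec$shape,
                                                     scale = spec$scale),
            normal = stats::rnorm(n, spec$mean, spec$sd),
            lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
            .stopf("unknown continuous distribution '%s'", spec$dist))
          if (!is.null(spec$min)) x <- pmax(x, spec$min)
          if (!is.null(spec$max)) x <- pmin(x, spec$max)
          x
        },
        .stopf("unknown covariate kind '%s'", spec$kind))
    })
    out[[spec$name]] <- v
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# Softmax treatment assignment probabilities (n x K).
.assignment_probs <- function(config, covariates) {
  D <- .eval_terms(config$ps_terms, covariates)
  eta <- D %*% t(config$ps_coefficients[config$arms, colnames(D), drop = FALSE])
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta)
  p / rowSums(p)
}

# Per-patient covariate linear predictor on the logit monthly MACE hazard.
.hazard_lp <- function(config, covariates) {
  if (!length(config$hazard_terms)) return(rep(0, nrow(covariates)))
  D <- .eval_terms(config$hazard_terms, covariates)
  drop(D[, -1L, drop = FALSE] %*%
         config$hazard_coefficients[names(config$hazard_terms)])
}

# Monthly hazard matrix (n x 60) for everyone assigned `arm`.
.hazard_matrix <- function(config, covariates, arm, horizon = HORIZON_MONTHS) {
  lp <- .hazard_lp(config, covariates)
  h0 <- config$baseline_hazard[seq_len(horizon)]
  base <- stats::qlogis(pmin(pmax(h0, 1e-12), 1 - 1e-12))
  eta <- outer(lp + config$arm_log_hazard[[arm]], rep(1, horizon)) +
    matrix(base, nrow = length(lp), ncol = horizon, byrow = TRUE)
  h <- stats::plogis(eta)
  h[, h0 == 0] <- 0
  h[, h0 == 1] <- 1
  h
}

#' Exact marginal cumulative incidence under an assigned strategy
#'
#' Computes the ground-truth cause-specific cumulative incidence
#' 1 - prod_t(1 - h_t), averaged (optionally with weights) over a supplied
#' covariate sample, under "everyone assigned `arm`". Competing
#' non-cardiovascular death is treated as censoring, matching the estimand of
#' the discrete-time hazard models.
#'
#' @param config A [sim_config()] object.
#' @param arm Strategy label.
#' @param population Data frame of baseline covariates (one row per patient).
#' @param horizon Months of follow-up (0-60).
#' @param weights Optional non-negative per-patient weights (e.g. overlap
#'   weights, to read off the truth in the overlap population).
#' @return A single probability.
#' @export
true_marginal_risk <- function(config, arm, population,
                               horizon = HORIZON_MONTHS, weights = NULL) {
  validate_sim_config(config)
  if (!arm %in% config$arms) .stopf("unknown arm label '%s'", arm)
  if (horizon > HORIZON_MONTHS) .stopf("horizon must be at most %d months",
                                       HORIZON_MONTHS)
  if (horizon == 0) return(0)
  h <- .hazard_matrix(config, population, arm, horizon)
  risk <- 1 - exp(rowSums(log1p(-h)))
  if (is.null(weights)) mean(risk) else sum(weights * risk) / sum(weights)
}

#' Generate synthetic linked EHR tables
#'
#' Simulates the full linked-table structure: `patients` (registration,
#' linkage eligibility, SMI diagnosis, baseline covariates), `prescriptions`
#' (monthly issues of the initiated antipsychotic, with switch / addition /
#' discontinuation patterns, pro re nata and long-acting injectable flags),
#' `episodes` (hospital admissions with ICD-10 primary diagnoses: I21* for
#' MI, I60*-I64* for stroke, plus comorbidity admissions), `deaths`
#' (registrations with underlying-cause ICD-10; deaths within 28 days of an
#' MI/stroke admission are emitted for a fraction of events), and
#' `adverse_reaction_codes`. Ground truth (assignment, linear predictors,
#' event realisations) is attached as `attr(, "truth")`.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `mace_raw_tables` with elements `patients`,
#'   `prescriptions`, `episodes`, `deaths`, `adverse_reaction_codes`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_patients
  seed <- config$seed
  arms <- config$arms
  id <- seq_len(n)

  covs <- .draw_covariates(config)

  # Treatment assignment by softmax over the confounded linear predictors.
  p_assign <- .assignment_probs(config, covs)
  arm_idx <- .substream(seed, "assignment", {
    u <- stats::runif(n)
    cp <- t(apply(p_assign, 1, cumsum))
    .first_true(cp >= u)
  })
  arm <- arms[pmin(arm_idx, 4L)]

  # Monthly competing event process: MACE first, then non-CV death among
  # those MACE-free that month.
  H <- matrix(0, n, HORIZON_MONTHS)
  for (a in arms) {
    rows <- arm == a
    if (any(rows)) H[rows, ] <- .hazard_matrix(config, covs[rows, , drop = FALSE], a)
  }
  u_mace <- .substream(seed, "events",
                       matrix(stats::runif(n * HORIZON_MONTHS), nrow = n,
                              byrow = TRUE))
  u_death <- .substream(seed, "deaths",
                        matrix(stats::runif(n * HORIZON_MONTHS), nrow = n,
                               byrow = TRUE))
  D <- matrix(config$noncv_death_hazard, n, HORIZON_MONTHS, byrow = TRUE)
  mace_m <- u_mace < H
  death_m <- !mace_m & (u_death < D)
  term <- .first_true(mace_m | death_m)          # 61 = completed horizon
  t_term <- pmin(term, HORIZON_MONTHS + 1L)
  has_mace <- term <= HORIZON_MONTHS & mace_m[cbind(id, pmin(term, HORIZON_MONTHS))]
  has_noncv <- term <= HORIZON_MONTHS & !has_mace
  followup_m <- ifelse(term > HORIZON_MONTHS, HORIZON_MONTHS, term)

  # MACE typing and the 28-day fatality process.
  et <- config$event_type_probs[c("mi", "stroke", "cv_death")]
  type_u <- .substream(seed, "event_type", stats::runif(n))
  fatal_u <- .substream(seed, "fatal", stats::runif(n))
  fatal_delay <- .substream(seed, "fatal_delay",
                            sample.int(29, n, replace = TRUE) - 1L)
  mace_type <- c("mi", "stroke", "cv_death")[findInterval(
    type_u, cumsum(et / sum(et))[-3L]) + 1L]
  is_fatal <- mace_type %in% c("mi", "stroke") & fatal_u < config$fatal_28day_prob

  # Adherence: geometric time to first strategy deviation.
  adh <- config$adherence
  q <- adh$monthly_deviation[arm]
  if (!is.null(adh$terms) && length(adh$terms)) {
    Dq <- .eval_terms(adh$terms, covs)[, -1L, drop = FALSE]
    q <- stats::plogis(stats::qlogis(pmin(pmax(q, 1e-12), 1 - 1e-12)) +
                         drop(Dq %*% adh$coefficients))
  }
  dev_month <- .substream(seed, "adherence", {
    g <- stats::rgeom(n, pmax(q, 1e-12)) + 1L
    g[q <= 0] <- NA_integer_
    g
  })
  dev_type_u <- .substream(seed, "deviation_type", stats::runif(n))
  split <- adh$split[c("switch", "addition", "discontinuation")]
  dev_type <- c("switch", "addition", "discontinuation")[findInterval(
    dev_type_u, cumsum(split / sum(split))[-3L]) + 1L]
  new_drug_u <- .substream(seed, "new_drug", stats::runif(n))
  adr_u <- .substream(seed, "adverse_reaction", stats::runif(n))
  adr_delay <- .substream(seed, "adverse_reaction_delay",
                          sample.int(30, n, replace = TRUE) - 1L)

  # Eligibility-violation seeding (disjoint single violations).
  viol_u <- .substream(seed, "violations", stats::runif(n))
  vr <- config$eligibility_violations
  edges <- cumsum(vr)
  viol <- rep(NA_character_, n)
  hit <- viol_u < edges[length(edges)]
  viol[hit] <- names(vr)[findInterval(viol_u[hit], c(0, edges),
                                      rightmost.closed = TRUE)]

  # Calendar scaffolding.
  win <- config$recruitment_window
  n_days <- as.integer(win[2] - win[1])
  index_date <- .substream(seed, "dates",
                           win[1] + floor(stats::runif(n) * (n_days + 1)))
  reg_gap <- .substream(seed, "registration",
                        183 + round(stats::rexp(n, 1 / 900)))
  short_reg <- !is.na(viol) & viol == "short_registration"
  reg_gap[short_reg] <- .substream(seed, "registration_short",
                                   sample.int(180, n,
                                              replace = TRUE))[short_reg]
  registration_date <- index_date - reg_gap
  smi_gap <- .substream(seed, "smi_gap", round(stats::rexp(n, 1 / 1800)))
  smi_date <- index_date - smi_gap
  late_smi <- !is.na(viol) & viol == "late_smi"
  smi_date[late_smi] <- index_date[late_smi] +
    .substream(seed, "smi_late", sample(31:365, n, replace = TRUE))[late_smi]
  smi_date[!is.na(viol) & viol == "no_smi"] <- NA
  linkage <- !(viol %in% "not_linkage")
  age_cov <- covs$age
  under <- !is.na(viol) & viol == "underage"
  age_at_index <- age_cov
  age_at_index[under] <- .substream(seed, "underage",
                                    sample(18:39, n, replace = TRUE))[under]
  birth_year <- as.integer(format(index_date, "%Y")) - round(age_at_index)
  dereg <- !is.na(viol) & viol == "deregistration"
  dereg_month <- rep(NA_integer_, n)
  dereg_month[dereg] <- .substream(seed, "dereg",
                                   sample.int(HORIZON_MONTHS, n,
                                              replace = TRUE))[dereg]
  dereg_date <- index_date + ifelse(is.na(dereg_month), NA,
                                    .day_of_month(dereg_month))

  patients <- data.frame(
    patient_id = id, birth_year = birth_year,
    sex = covs$sex, ethnicity = covs$ethnicity,
    imd_quintile = covs$imd_quintile,
    registration_date = registration_date,
    practice_linkage_eligible = linkage,
    smi_diagnosis_date = as.Date(smi_date),
    smi_diagnosis_type = covs$smi_diagnosis,
    diabetes = covs$diabetes, hypertension = covs$hypertension,
    smoking = covs$smoking, bmi = covs$bmi,
    prior_antipsychotic = covs$prior_antipsychotic,
    history_cvd_dementia = !is.na(viol) & viol == "prior_cvd_dementia",
    deregistration_date = as.Date(dereg_date),
    last_collection_date = as.Date("2019-12-31"),
    stringsAsFactors = FALSE)

  # Prescriptions: monthly issues of the initiated drug until deviation,
  # deregistration, or the terminal month; switch/addition patterns after.
  ddd <- ddd_table()
  native_dose <- covs$starting_dose * ddd[arm] / ddd["olanzapine"]
  end_m <- followup_m
  end_m[dereg] <- pmin(end_m[dereg], dereg_month[dereg])
  dev_eff <- ifelse(!is.na(dev_month) & dev_month < end_m, dev_month, NA)
  own_end <- ifelse(!is.na(dev_eff) & dev_type != "addition", dev_eff, end_m)
  own_end <- pmax(own_end, 1L)

  rx_n <- own_end
  rx_pid <- rep(id, rx_n)
  rx_month <- sequence(rx_n)
  rx <- data.frame(
    patient_id = rx_pid,
    date = index_date[rx_pid] + round((rx_month - 1) * DAYS_PER_MONTH),
    drug = arm[rx_pid],
    daily_dose_mg = round(native_dose[rx_pid], 1),
    pro_re_nata = FALSE, long_acting_injectable = FALSE,
    stringsAsFactors = FALSE)
  rx$pro_re_nata[rx_month == 1L & rx_pid %in% id[viol %in% "prn_first"]] <- TRUE

  # Second drug after a switch or addition.
  pools <- t(vapply(1:4, function(k) setdiff(seq_len(4), k), integer(3)))
  other <- arms[pools[cbind(pmin(arm_idx, 4L),
                            pmin(3L, 1L + floor(new_drug_u * 3)))]]
  sw <- which(!is.na(dev_eff) & dev_type %in% c("switch", "addition") &
                dev_eff < end_m)
  if (length(sw)) {
    n2 <- end_m[sw] - dev_eff[sw]
    p2 <- rep(sw, n2)
    m2 <- sequence(n2) + dev_eff[p2]
    rx2 <- data.frame(
      patient_id = p2,
      date = index_date[p2] + round((m2 - 1) * DAYS_PER_MONTH),
      drug = other[p2],
      daily_dose_mg = round(native_dose[p2], 1),
      pro_re_nata = FALSE, long_acting_injectable = FALSE,
      stringsAsFactors = FALSE)
    rx <- rbind(rx, rx2)
  }

  lai <- which(viol %in% "lai_prior")
  if (length(lai)) {
    lai_gap <- .substream(seed, "lai", sample(10:89, n, replace = TRUE))
    rx <- rbind(rx, data.frame(
      patient_id = lai, date = index_date[lai] - lai_gap[lai],
      drug = arm[lai], daily_dose_mg = round(native_dose[lai], 1),
      pro_re_nata = FALSE, long_acting_injectable = TRUE,
      stringsAsFactors = FALSE))
  }
  cop <- which(viol %in% "coprescribed")
  if (length(cop)) {
    rx <- rbind(rx, data.frame(
      patient_id = cop, date = index_date[cop], drug = other[cop],
      daily_dose_mg = round(native_dose[cop], 1),
      pro_re_nata = FALSE, long_acting_injectable = FALSE,
      stringsAsFactors = FALSE))
  }
  rx <- rx[order(rx$patient_id, rx$date, rx$drug), ]
  rownames(rx) <- NULL

  # Episodes: MACE admissions, prior-history admissions, comorbidity onsets.
  mi_codes <- c("I210", "I214", "I219")
  stroke_codes <- c("I609", "I619", "I639", "I649")
  code_u <- .substream(seed, "icd", stats::runif(n))
  ep <- list()
  adm <- which(has_mace & mace_type %in% c("mi", "stroke"))
  if (length(adm)) {
    codes <- ifelse(mace_type[adm] == "mi",
                    mi_codes[1L + floor(code_u[adm] * 3)],
                    stroke_codes[1L + floor(code_u[adm] * 4)])
    ep$mace <- data.frame(
      patient_id = adm,
      admission_date = index_date[adm] + .day_of_month(followup_m[adm]),
      primary_icd10 = codes, stringsAsFactors = FALSE)
  }
  hist_i <- which(patients$history_cvd_dementia)
  if (length(hist_i)) {
    hist_gap <- .substream(seed, "history", sample(200:1500, n, replace = TRUE))
    hist_codes <- c("I219", "I639", "F009", "G309")
    ep$history <- data.frame(
      patient_id = hist_i,
      admission_date = index_date[hist_i] - hist_gap[hist_i],
      primary_icd10 = hist_codes[1L + floor(code_u[hist_i] * 4)],
      stringsAsFactors = FALSE)
  }
  com_codes <- c("E119", "I109", "J449", "N189", "K769", "M810")
  com_m <- .substream(seed, "comorbidity",
                      matrix(stats::runif(n * HORIZON_MONTHS), nrow = n,
                             byrow = TRUE)) < config$comorbidity_onset_prob
  com_m <- com_m & (col(com_m) <= followup_m)
  ci <- which(com_m, arr.ind = TRUE)
  if (nrow(ci)) {
    ep$comorbidity <- data.frame(
      patient_id = ci[, 1],
      admission_date = index_date[ci[, 1]] + .day_of_month(ci[, 2]) - 3,
      primary_icd10 = com_codes[1L + (ci[, 1] + ci[, 2]) %% 6L],
      stringsAsFactors = FALSE)
  }
  episodes <- do.call(rbind, unname(ep))
  if (is.null(episodes)) {
    episodes <- data.frame(patient_id = integer(0),
                           admission_date = as.Date(character(0)),
                           primary_icd10 = character(0))
  }
  episodes <- episodes[order(episodes$patient_id, episodes$admission_date), ]
  rownames(episodes) <- NULL

  # Deaths.
  cv_cause <- c("I251", "I219", "I639", "I489")
  noncv_cause <- c("C809", "J189", "C349", "K746")
  dth <- list()
  dcv <- which(has_mace & mace_type == "cv_death")
  if (length(dcv)) {
    dth$cv <- data.frame(
      patient_id = dcv,
      date = index_date[dcv] + .day_of_month(followup_m[dcv]),
      underlying_cause_icd10 = cv_cause[1L + floor(code_u[dcv] * 4)],
      stringsAsFactors = FALSE)
  }
  dfat <- which(has_mace & is_fatal & mace_type %in% c("mi", "stroke"))
  if (length(dfat)) {
    # underlying cause occasionally non-circulatory; the 28-day rule governs.
    cause <- ifelse(code_u[dfat] < 0.8, cv_cause[1L + floor(code_u[dfat] * 4)],
                    noncv_cause[1L + floor(code_u[dfat] * 4)])
    dth$fatal <- data.frame(
      patient_id = dfat,
      date = index_date[dfat] + .day_of_month(followup_m[dfat]) +
        fatal_delay[dfat],
      underlying_cause_icd10 = cause, stringsAsFactors = FALSE)
  }
  dnc <- which(has_noncv)
  if (length(dnc)) {
    dth$noncv <- data.frame(
      patient_id = dnc,
      date = index_date[dnc] + .day_of_month(followup_m[dnc]),
      underlying_cause_icd10 = noncv_cause[1L + floor(code_u[dnc] * 4)],
      stringsAsFactors = FALSE)
  }
  deaths <- do.call(rbind, unname(dth))
  if (is.null(deaths)) {
    deaths <- data.frame(patient_id = integer(0), date = as.Date(character(0)),
                         underlying_cause_icd10 = character(0))
  }
  deaths <- deaths[order(deaths$patient_id), ]
  rownames(deaths) <- NULL

  # Adverse-reaction codes near a fraction of strategy deviations.
  adr_i <- which(!is.na(dev_eff) & adr_u < config$adverse_reaction_prob)
  if (length(adr_i)) {
    base_day <- ifelse(dev_type[adr_i] == "discontinuation",
                       round((dev_eff[adr_i] - 1) * DAYS_PER_MONTH),
                       round(dev_eff[adr_i] * DAYS_PER_MONTH))
    adverse <- data.frame(
      patient_id = adr_i,
      date = index_date[adr_i] + base_day + adr_delay[adr_i],
      drug = arm[adr_i], stringsAsFactors = FALSE)
  } else {
    adverse <- data.frame(patient_id = integer(0),
                          date = as.Date(character(0)), drug = character(0))
  }

  truth <- data.frame(
    patient_id = id, arm = arm, hazard_lp = .hazard_lp(config, covs),
    mace_month = ifelse(has_mace, followup_m, NA_integer_),
    mace_type = ifelse(has_mace, mace_type, NA_character_),
    fatal_28day = has_mace & is_fatal & mace_type %in% c("mi", "stroke"),
    noncv_death_month = ifelse(has_noncv, followup_m, NA_integer_),
    deviation_month = dev_eff,
    deviation_type = ifelse(is.na(dev_eff), NA_character_, dev_type),
    violation = viol, stringsAsFactors = FALSE)

  structure(list(patients = patients, prescriptions = rx, episodes = episodes,
                 deaths = deaths, adverse_reaction_codes = adverse),
            class = "mace_raw_tables",
            truth = truth, config = config)
}

#' Pre-specified simulation scenarios
#'
#' Named study conditions used throughout the package's validation:
#' \describe{
#'   \item{null}{No treatment effect; treatment assignment confounded by age
#'     and diabetes (channelling by age and metabolic comorbidity), with MAR
#'     missingness in BMI. The confounder set is `c("age", "diabetes")`.}
#'   \item{protective}{As `null`, with a protective aripiprazole effect of
#'     log(0.8) on the logit monthly hazard (a rare-event risk ratio of about
#'     0.8 over five years).}
#'   \item{informative_censoring}{No assignment confounding; strategy
#'     deviation strongly driven by diabetes (log-odds +2.2/month), which
#'     also raises the MACE hazard (log-odds +1.2) and is common (35%), so
#'     naive per-protocol estimates are biased and censoring weights have
#'     something to correct.}
#'   \item{rare_event}{A true aripiprazole hazard ratio of 0.6 with a raised
#'     baseline hazard (0.002/month, still rare per month) and no adherence
#'     process: the regime where discrete-time and Cox hazard ratios agree.}
#' }
#' The modelled confounder set for each scenario is attached as
#' `attr(, "confounders")` and the matching propensity formula as
#' `attr(, "ps_formula")`.
#'
#' @param scenario Scenario name.
#' @param n_patients Cohort size.
#' @param seed Master seed.
#' @return A [sim_config()].
#' @export
scenario_config <- function(scenario = c("null", "protective",
                                         "informative_censoring",
                                         "rare_event"),
                            n_patients = 20000, seed) {
  scenario <- match.arg(scenario)
  pc <- matrix(0, 4, 9,
               dimnames = list(study_drugs(),
                               c("(intercept)", names(.default_ps_terms()))))
  pc[, "(intercept)"] <- c(0, 1.48, 1.13, 1.02)
  pc[, "age10"] <- c(0, 0.10, 0.45, 0.75)
  pc[, "diabetes"] <- c(0, -0.50, -0.40, -0.45)
  args <- list(n_patients = n_patients, seed = seed, ps_coefficients = pc,
               missingness_spec = list(
                 bmi = list(terms = c(male = "sex == 'male'"),
                            coefficients = c(-1.50, -0.30))))
  confounders <- c("age", "diabetes")
  if (scenario == "protective") {
    args$arm_log_hazard <- stats::setNames(c(log(0.8), 0, 0, 0),
                                           study_drugs())
  }
  if (scenario == "informative_censoring") {
    args$ps_coefficients[, c("age10", "diabetes")] <- 0
    args$missingness_spec <- list()
    cs <- default_covariate_spec()
    cs[[which(vapply(cs, `[[`, "", "name") == "diabetes")]]$prob <- 0.35
    args$covariate_spec <- cs
    args$hazard_coefficients <- c(age10 = 0.70, male = 0.30, diabetes = 1.20,
                                  smoker = 0.50, hypertension = 0.30,
                                  bmi6 = 0.15)
    args$adherence <- list(
      monthly_deviation = stats::setNames(rep(0.004, 4), study_drugs()),
      split = c(switch = 0.3, addition = 0.2, discontinuation = 0.5),
      terms = c(diabetes = "diabetes"), coefficients = 2.2)
  }
  if (scenario == "rare_event") {
    args$arm_log_hazard <- stats::setNames(c(log(0.6), 0, 0, 0),
                                           study_drugs())
    args$baseline_hazard <- 0.002
    args$adherence <- list(
      monthly_deviation = stats::setNames(rep(0, 4), study_drugs()),
      split = c(switch = 0.3, addition = 0.2, discontinuation = 0.5),
      terms = NULL, coefficients = NULL)
    args$missingness_spec <- list()
  }
  cfg <- do.call(sim_config, args)
  attr(cfg, "confounders") <- confounders
  attr(cfg, "ps_formula") <- stats::as.formula(
    paste("~", paste(confounders, collapse = " + ")))
  cfg
}

#' Mask covariates missing-at-random
#'
#' Applies the configured per-covariate MAR logistic missingness models to the
#' `patients` table. Missingness may depend only on fully observed fields;
#' treatment and outcome fields are never maskable. The pre-masking complete
#' table is retained as `attr(, "complete_patients")` for recovery tests.
#'
#' @param tables A `mace_raw_tables` object.
#' @param config The generating [sim_config()].
#' @return The tables with masked `patients` covariate cells.
#' @export
apply_missingness <- function(tables, config) {
  stopifnot(inherits(tables, "mace_raw_tables"))
  validate_sim_config(config)
  pats <- tables$patients
  complete <- pats
  for (v in names(config$missingness_spec)) {
    if (!v %in% c(names(pats), "starting_dose")) {
      .stopf("missingness_spec names unknown field '%s'", v)
    }
    spec <- config$missingness_spec[[v]]
    D <- .eval_terms(spec$terms, complete)
    p <- stats::plogis(drop(D %*% spec$coefficients))
    u <- .substream(config$seed, paste0("missing:", v),
                    stats::runif(nrow(pats)))
    if (v == "starting_dose") {
      # dose lives on the prescription: mask the index (first) issue's dose
      rx <- tables$prescriptions
      first <- !duplicated(rx$patient_id) & !rx$long_acting_injectable
      hit <- rx$patient_id[first][
        (u < p)[match(rx$patient_id[first], pats$patient_id)]]
      rx$daily_dose_mg[first & rx$patient_id %in% hit] <- NA
      tables$prescriptions <- rx
    } else {
      pats[[v]][u < p] <- NA
    }
  }
  tables$patients <- pats
  attr(tables, "complete_patients") <- complete
  tables
}

#' @export
print.mace_raw_tables <- function(x, ...) {
  cat("Synthetic linked EHR tables\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %8d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
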