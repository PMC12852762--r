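# Inverse-probability-of-censoring weights for the per-protocol estimand.

#' Censoring-model specification
#'
#' @param covariate_set `"baseline_only"` or `"baseline_plus_timevarying"`
#'   (adds a monthly cumulative count of distinct comorbidity categories
#'   recorded during follow-up).
#' @param covariates Baseline covariates entering the denominator model.
#' @param stabilised Use a numerator model with arm and time only.
#' @param trim_percentile Percentile at which cumulative weights are capped.
#' @param include_admin Model deregistration / last-collection censoring
#'   together with strategy-deviation censoring (both require prescription
#'   records); switch off to model strategy deviations only.
#' @return An object of class `censor_model_spec`.
#' @export
censor_model_spec <- function(covariate_set = c("baseline_only",
                                                "baseline_plus_timevarying"),
                              covariates = covariate_names(),
                              stabilised = TRUE,
                              trim_percentile = 99.5,
                              include_admin = TRUE) {
  covariate_set <- match.arg(covariate_set)
  if (!(trim_percentile > 50 && trim_percentile <= 100)) {
    .stopf("trim percentile must lie in (50, 100]")
  }
  structure(list(covariate_set = covariate_set, covariates = covariates,
                 stabilised = stabilised, trim_percentile = trim_percentile,
                 include_admin = include_admin),
            class = "censor_model_spec")
}

#' Monthly cumulative comorbidity counts
#'
#' Number of distinct comorbidity categories (non-MACE admission diagnoses)
#' recorded up to and including each month of follow-up, per patient: the
#' time-varying term of the extended censoring model.
#'
#' @param cohort Cohort with index dates.
#' @param episodes Raw admissions table.
#' @param horizon Months.
#' @return Integer matrix, patients x months.
#' @export
comorbidity_counts <- function(cohort, episodes, horizon = HORIZON_MONTHS) {
  n <- nrow(cohort)
  out <- matrix(0L, n, horizon)
  if (is.null(episodes) || !nrow(episodes)) return(out)
  m <- match(episodes$patient_id, cohort$patient_id)
  day <- as.numeric(episodes$admission_date - cohort$index_date[m])
  keep <- !is.na(m) & day >= 0 &
    !grepl(paste0(.MI_RE, "|", .STROKE_RE), episodes$primary_icd10)
  if (!any(keep)) return(out)
  pid <- m[keep]
  mon <- pmin(month_of_day(day[keep]), horizon)
  cat3 <- substr(episodes$primary_icd10[keep], 1, 3)
  first <- !duplicated(paste(pid, cat3))
  inc <- matrix(0L, n, horizon)
  sel <- cbind(pid[first], mon[first])
  for (r in seq_len(nrow(sel))) inc[sel[r, 1], sel[r, 2]] <-
      inc[sel[r, 1], sel[r, 2]] + 1L
  t(apply(inc, 1, cumsum))
}

#' Fit the per-protocol censoring models
#'
#' Pooled logistic models for the time-dependent probability of per-protocol
#' censoring per person-month: the numerator (stabilisation) model contains
#' arm and time only; the denominator adds baseline covariates and, for the
#' extended specification, the monthly cumulative comorbidity count.
#' Artificial (strategy-deviation) censoring is modelled; administrative
#' reasons are included per the specification switch. Arms without any
#' censoring events get probability-one weights with a warning.
#'
#' @param cohort Cohort with ITT and per-protocol follow-up derived.
#' @param spec A [censor_model_spec()].
#' @param comorbidity Optional patients x months matrix from
#'   [comorbidity_counts()] (required for the time-varying specification).
#' @param horizon Months.
#' @return A `censor_model` with per-patient-month probabilities of remaining
#'   uncensored under the numerator and denominator models.
#' @export
fit_censoring_model <- function(cohort, spec = censor_model_spec(),
                                comorbidity = NULL,
                                horizon = HORIZON_MONTHS) {
  if (!"pp_censor_month" %in% names(cohort)) {
    .stopf("per-protocol censoring must be derived first")
  }
  term <- .outcome_terminal(cohort, "pp", "mace", horizon)
  reasons <- c("switch", "addition", "discontinuation")
  if (spec$include_admin) {
    reasons <- c(reasons, "deregistration", "last_collection")
  }
  cens <- !is.na(cohort$pp_censor_month) &
    cohort$pp_censor_reason %in% reasons &
    cohort$pp_censor_month <= term$term & !term$event
  n <- nrow(cohort)
  T_i <- term$term
  idx <- rep(seq_len(n), T_i)
  month <- sequence(T_i)
  y <- as.integer(month == T_i[idx] & cens[idx])
  df <- data.frame(y = y, month = month, time = month / 12,
                   arm = cohort$arm[idx])
  no_cens_arms <- setdiff(levels(cohort$arm),
                          unique(as.character(df$arm[df$y == 1])))
  if (length(no_cens_arms)) {
    warning(sprintf("no per-protocol censoring in arm(s) %s: weights set to 1",
                    paste(no_cens_arms, collapse = ", ")))
  }
  num_fit <- suppressWarnings(stats::glm(y ~ arm + time, data = df,
                                         family = stats::binomial()))
  den_df <- cbind(df, cohort[idx, spec$covariates, drop = FALSE])
  rhs <- paste(c("arm", "time", spec$covariates), collapse = " + ")
  if (spec$covariate_set == "baseline_plus_timevarying") {
    if (is.null(comorbidity)) {
      .stopf("time-varying specification requires a comorbidity count matrix")
    }
    den_df$comorbidity_count <- comorbidity[cbind(idx, month)]
    rhs <- paste(rhs, "+ comorbidity_count")
  }
  den_fit <- suppressWarnings(stats::glm(
    stats::as.formula(paste("y ~", rhs)), data = den_df,
    family = stats::binomial()))
  p_num <- stats::fitted(num_fit)
  p_den <- stats::fitted(den_fit)
  zero <- as.character(df$arm) %in% no_cens_arms
  p_num[zero] <- 0
  p_den[zero] <- 0
  structure(list(patient = idx, month = month,
                 p_uncens_num = 1 - p_num, p_uncens_den = 1 - p_den,
                 T_i = T_i, n = n, spec = spec,
                 num_fit = num_fit, den_fit = den_fit),
            class = "censor_model")
}

#' Inverse-probability-of-censoring weights
#'
#' Cumulative product over preceding months of the stabilised ratio of
#' remaining-uncensored probabilities, numerator over denominator; the weight
#' for month 1 is exactly 1 (censoring is assessed at month end). Weights are
#' capped at the configured percentile of the person-month weight
#' distribution, and are combined multiplicatively with the treatment weights
#' downstream.
#'
#' @param model A `censor_model` from [fit_censoring_model()].
#' @return A patients x months matrix of censoring weights (1 beyond each
#'   patient's follow-up), with the cap value as `attr(, "trim_value")`.
#' @export
ipcw <- function(model) {
  spec <- model$spec
  W <- matrix(1, model$n, max(model$T_i))
  ratio <- if (spec$stabilised) {
    model$p_uncens_num / model$p_uncens_den
  } else {
    1 / model$p_uncens_den
  }
  if (any(!is.finite(ratio))) {
    .stopf("censoring-probability underflow: consider trimming or %s",
           "a sparser denominator model")
  }
  sp <- split(ratio, model$patient)
  for (i in seq_along(sp)) {
    r <- sp[[i]]
    Ti <- length(r)
    if (Ti > 1) W[i, 2:Ti] <- cumprod(r[-Ti])   # lagged: month 1 weight is 1
  }
  used <- W[cbind(model$patient, model$month)]
  trim_value <- NA_real_
  if (!is.na(spec$trim_percentile)) {
    trim_value <- stats::quantile(used, spec$trim_percentile / 100,
                                  names = FALSE)
    W <- pmin(W, trim_value)
  }
  attr(W, "trim_value") <- trim_value
  W
}
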