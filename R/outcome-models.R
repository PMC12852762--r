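# Discrete-time outcome modelling: person-month expansion, weighted pooled
# logistic hazard models, g-formula risk standardisation, contrasts, hazard
# ratios (discrete-time and Cox), and effect-modification tests.

# Terminal month and event indicator for a chosen estimand/outcome.
.outcome_terminal <- function(cohort, estimand = c("itt", "pp"),
                              outcome = c("mace", "mi", "stroke", "cv_death"),
                              horizon = HORIZON_MONTHS) {
  estimand <- match.arg(estimand)
  outcome <- match.arg(outcome)
  if (outcome == "mace") {
    ev_month <- cohort$itt_event_month
    cens <- ifelse(is.na(cohort$itt_censor_month), horizon,
                   cohort$itt_censor_month)
  } else {
    ev_month <- cohort[[paste0(sub("^cv_death$", "cv_death_event",
                                   sub("^(mi|stroke)$", "\\1_event", outcome)),
                               "_month")]]
    # Component follow-up is censored at component incidence or death, never
    # at another non-fatal component.
    death <- cohort$death_month
    cens <- pmin(ifelse(is.na(death), horizon, death), horizon)
  }
  term <- pmin(ifelse(is.na(ev_month), horizon + 1L, ev_month), cens)
  term <- pmin(term, horizon)
  event <- !is.na(ev_month) & ev_month <= term   # event-first tie resolution
  if (estimand == "pp") {
    pp <- cohort$pp_censor_month
    has_pp <- !is.na(pp)
    new_term <- ifelse(has_pp, pmin(term, pp), term)
    event <- event & (ifelse(is.na(ev_month), Inf, ev_month) <= new_term)
    term <- new_term
  }
  list(term = pmax(as.integer(term), 1L), event = event)
}

#' Expand a cohort into a person-month table
#'
#' One row per patient per month at risk: a patient with terminal month T
#' contributes months 1..T, with the event indicator set only in the final
#' month when follow-up ends in the chosen outcome. The per-protocol estimand
#' truncates follow-up at the per-protocol censoring month.
#'
#' @param cohort Cohort with follow-up derived (and per-protocol columns for
#'   `estimand = "pp"`).
#' @param estimand `"itt"` or `"pp"`.
#' @param outcome Composite `"mace"` or a component.
#' @param weights Optional per-patient base weights (`weight_set` or vector).
#' @param horizon Months of follow-up.
#' @return A `person_month` data frame with columns patient_id, month, arm,
#'   event, weight.
#' @export
expand_person_months <- function(cohort, estimand = c("itt", "pp"),
                                 outcome = c("mace", "mi", "stroke",
                                             "cv_death"),
                                 weights = NULL, horizon = HORIZON_MONTHS) {
  term <- .outcome_terminal(cohort, estimand, outcome, horizon)
  w <- if (inherits(weights, "weight_set")) weights$weights
       else if (is.null(weights)) rep(1, nrow(cohort)) else weights
  T_i <- term$term
  idx <- rep(seq_len(nrow(cohort)), T_i)
  month <- sequence(T_i)
  pm <- data.frame(patient_id = cohort$patient_id[idx], month = month,
                   arm = cohort$arm[idx],
                   event = as.integer(month == T_i[idx] & term$event[idx]),
                   weight = w[idx])
  class(pm) <- c("person_month", "data.frame")
  attr(pm, "horizon") <- horizon
  pm
}

# Aggregate person-months into (arm, month) cells of weighted at-risk mass
# and weighted events -- an exact sufficient reduction for hazard models whose
# covariates are functions of arm and month only.
.aggregate_cells <- function(T_i, event, arm, w, horizon = HORIZON_MONTHS,
                             wm = NULL) {
  arms <- levels(arm)
  out <- vector("list", length(arms))
  for (k in seq_along(arms)) {
    rows <- which(as.integer(arm) == k)
    Tk <- T_i[rows]
    if (is.null(wm)) {
      wk <- w[rows]
      totals <- rowsum(wk, Tk)                     # weight mass ending month t
      byT <- numeric(horizon)
      byT[as.integer(rownames(totals))] <- totals
      atrisk <- rev(cumsum(rev(byT)))              # at risk in month t
      evk <- rowsum(wk * event[rows], Tk)
      ev <- numeric(horizon)
      ev[as.integer(rownames(evk))] <- evk
    } else {
      # person-month weights vary over time (IPCW): wm holds the full
      # product weight per patient-month; mask beyond T_i and column-sum
      W <- wm[rows, seq_len(horizon), drop = FALSE]
      W[outer(Tk, seq_len(horizon), `<`)] <- 0
      atrisk <- colSums(W)
      ev <- numeric(horizon)
      ei <- rows[event[rows]]
      if (length(ei)) {
        s <- rowsum(wm[cbind(ei, T_i[ei])], T_i[ei])
        ev[as.integer(rownames(s))] <- s
      }
    }
    out[[k]] <- data.frame(arm = arms[k], month = seq_len(horizon),
                           atrisk = atrisk, events = ev)
  }
  cells <- do.call(rbind, out)
  cells$arm <- factor(cells$arm, levels = arms)
  cells[cells$atrisk > 0, , drop = FALSE]
}

.pm_to_cells <- function(pm, horizon = NULL) {
  horizon <- horizon %||% attr(pm, "horizon") %||% max(pm$month)
  key <- interaction(pm$arm, pm$month, drop = FALSE)
  atrisk <- tapply(pm$weight, key, sum, default = 0)
  events <- tapply(pm$weight * pm$event, key, sum, default = 0)
  lv <- do.call(rbind, strsplit(names(atrisk), ".", fixed = TRUE))
  cells <- data.frame(arm = factor(lv[, 1], levels = levels(pm$arm)),
                      month = as.integer(lv[, 2]),
                      atrisk = as.numeric(atrisk),
                      events = as.numeric(events))
  cells <- cells[cells$atrisk > 0, , drop = FALSE]
  cells[order(cells$arm, cells$month), , drop = FALSE]
}

.hazard_design <- function(arm, month, arms, time_interaction, g_time,
                           spline_basis = NULL) {
  t_s <- month / 12                                # time in years, for scale
  if (g_time == "spline") {
    tb <- if (is.null(spline_basis)) splines::ns(t_s, df = 3)
          else stats::predict(spline_basis, t_s)
    colnames(tb) <- paste0("time_ns", seq_len(ncol(tb)))
  } else {
    tb <- matrix(t_s, ncol = 1, dimnames = list(NULL, "time"))
  }
  A <- matrix(0, length(arm), length(arms) - 1L,
              dimnames = list(NULL, paste0("arm_", arms[-1])))
  ai <- as.integer(factor(arm, levels = arms))
  for (k in 2:length(arms)) A[, k - 1L] <- as.numeric(ai == k)
  X <- cbind(`(Intercept)` = 1, tb, A)
  if (time_interaction) {
    AT <- A * t_s
    colnames(AT) <- paste0(colnames(A), ":time")
    X <- cbind(X, AT)
  }
  X
}

#' Fit a weighted pooled logistic hazard model
#'
#' Discrete-time hazard model on person-months:
#' logit h(t, arm) = alpha + g(t) + sum_k beta_k arm_k
#' (+ sum_k gamma_k arm_k * t when `time_interaction`). Because the model
#' covariates are functions of arm and month only, the fit uses the exact
#' sufficient aggregation of person-months into (arm, month) cells; product
#' weights (base x censoring) are supported through the cell masses.
#'
#' @param pm A `person_month` table from [expand_person_months()], or a
#'   pre-aggregated cell table with columns arm, month, atrisk, events.
#' @param time_interaction Include arm-by-time product terms (time-varying
#'   hazards).
#' @param g_time `"linear"` (default) or `"spline"` (natural cubic, 3 df).
#' @return A `hazard_model` with coefficients, the cell table, and model
#'   metadata.
#' @export
fit_pooled_logistic <- function(pm, time_interaction = TRUE,
                                g_time = c("linear", "spline")) {
  g_time <- match.arg(g_time)
  cells <- if (all(c("atrisk", "events") %in% names(pm))) pm
           else .pm_to_cells(pm)
  if (sum(cells$events) <= 0) .stopf("no events: cannot fit a hazard model")
  arms <- levels(cells$arm)
  zero_arm <- setdiff(arms, unique(as.character(cells$arm[cells$events > 0])))
  spline_basis <- if (g_time == "spline") splines::ns(cells$month / 12, df = 3)
                  else NULL
  X <- .hazard_design(cells$arm, cells$month, arms, time_interaction, g_time,
                      spline_basis = NULL)
  if (g_time == "spline") {
    X <- .hazard_design(cells$arm, cells$month, arms, time_interaction,
                        g_time, spline_basis = spline_basis)
  }
  y <- cells$events / cells$atrisk
  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = y, weights = cells$atrisk,
    family = stats::quasibinomial()))
  structure(list(coefficients = fit$coefficients, arms = arms,
                 time_interaction = time_interaction, g_time = g_time,
                 spline_basis = spline_basis, cells = cells,
                 zero_event_arms = zero_arm,
                 horizon = max(cells$month)),
            class = "hazard_model")
}

#' @export
print.hazard_model <- function(x, ...) {
  cat(sprintf("Pooled logistic hazard model (g(t) %s%s)\n", x$g_time,
              if (x$time_interaction) ", arm-by-time products" else ""))
  print(round(x$coefficients, 4))
  if (length(x$zero_event_arms)) {
    cat("unstable arms (zero events):",
        paste(x$zero_event_arms, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fitted monthly hazards under an assigned strategy
#'
#' @param model A `hazard_model`.
#' @param arm Strategy label.
#' @param horizon Months.
#' @return Numeric vector of monthly discrete hazards, in (0, 1).
#' @export
predict_hazard <- function(model, arm, horizon = NULL) {
  horizon <- horizon %||% model$horizon
  X <- .hazard_design(factor(rep(arm, horizon), levels = model$arms),
                      seq_len(horizon), model$arms, model$time_interaction,
                      model$g_time, spline_basis = model$spline_basis)
  stats::plogis(drop(X %*% model$coefficients))
}

#' Standardised cumulative-incidence curve under an assigned strategy
#'
#' g-formula standardisation of the fitted discrete hazards:
#' R(t) = 1 - prod_{u=1..t} (1 - h(u, arm)), with the arm indicator set to
#' the strategy. R(0) = 0 and the curve is non-decreasing and bounded by
#' construction.
#'
#' @param model A `hazard_model`.
#' @param arm Strategy label.
#' @param horizon Months (at most the model horizon grid of 60).
#' @return A `risk_curve` data frame with columns month (0..horizon) and risk.
#' @export
predict_risk_curve <- function(model, arm, horizon = NULL) {
  horizon <- horizon %||% model$horizon
  if (horizon > HORIZON_MONTHS) .stopf("horizon must be at most %d months",
                                       HORIZON_MONTHS)
  h <- predict_hazard(model, arm, horizon)
  risk <- c(0, 1 - cumprod(1 - h))
  stopifnot(all(diff(risk) >= -1e-12), all(risk >= 0 & risk <= 1))
  structure(data.frame(arm = arm, month = 0:horizon, risk = risk),
            class = c("risk_curve", "data.frame"))
}

#' Pairwise risk contrast at a horizon
#'
#' RD per 1000 = 1000 * (R_treat(h) - R_comp(h)); RR = R_treat(h) / R_comp(h).
#'
#' @param curve_treat,curve_comp `risk_curve`s sharing the horizon (treat =
#'   aripiprazole in the emulation's contrasts).
#' @param horizon Month at which risks are read (from the same fitted model,
#'   not a refit).
#' @return List with risks, `rd_per_1000`, and `rr` (NA, flagged, when the
#'   comparator risk is zero).
#' @export
risk_contrast <- function(curve_treat, curve_comp, horizon = 60) {
  r1 <- curve_treat$risk[match(horizon, curve_treat$month)]
  r0 <- curve_comp$risk[match(horizon, curve_comp$month)]
  if (is.na(r1) || is.na(r0)) .stopf("curves do not share horizon %d", horizon)
  rr <- if (r0 == 0) NA_real_ else r1 / r0
  list(risk_treat = r1, risk_comp = r0,
       rd_per_1000 = 1000 * (r1 - r0), rr = rr,
       rr_undefined = r0 == 0)
}

#' Approximate hazard ratios from the no-interaction pooled logistic model
#'
#' With rare per-month events, exp(beta_arm) from the pooled logistic model
#' without arm-by-time products approximates the Cox hazard ratio. Returned
#' as reference arm versus each comparator, exp(-beta_k).
#'
#' @param pm Person-month table or cell table (see [fit_pooled_logistic()]).
#' @return Named vector of hazard ratios (reference vs comparator).
#' @export
approximate_hr <- function(pm) {
  model <- fit_pooled_logistic(pm, time_interaction = FALSE)
  b <- model$coefficients[paste0("arm_", model$arms[-1])]
  stats::setNames(exp(-b), paste0(model$arms[1], "_vs_", model$arms[-1]))
}

#' Cox proportional hazards model on the day scale
#'
#' Continuous-time check on the discrete-time models: partial likelihood with
#' Efron tie handling and robust (sandwich) standard errors. Exact event/censor
#' days are used where derived; otherwise terminal months are placed mid-month
#' ((T - 0.5) * 30.4375 days). The covariate-adjusted variant enters baseline
#' covariates instead of weights.
#'
#' @param cohort Cohort with follow-up (and per-protocol columns for
#'   `estimand = "pp"`).
#' @param weights Optional `weight_set` or numeric weights (ignored when
#'   `covariate_adjusted`).
#' @param estimand,outcome As for [expand_person_months()].
#' @param covariate_adjusted Adjust for baseline covariates instead of
#'   weighting.
#' @param covariates Covariates for the adjusted variant.
#' @return List with per-contrast hazard ratios (reference vs comparator),
#'   robust standard errors of the log HRs, and the `survival::coxph` fit.
#' @export
fit_cox <- function(cohort, weights = NULL, estimand = "itt",
                    outcome = "mace", covariate_adjusted = FALSE,
                    covariates = covariate_names()) {
  term <- .outcome_terminal(cohort, estimand, outcome)
  if (!any(term$event)) .stopf("no events: cannot fit a Cox model")
  day <- cohort$itt_terminal_day
  day <- ifelse(is.na(day), (term$term - 0.5) * DAYS_PER_MONTH, day)
  # honour the discrete terminal (pp truncation, component censoring)
  day <- pmin(day, term$term * DAYS_PER_MONTH)
  df <- data.frame(time = pmax(day, 0.5), status = as.integer(term$event),
                   arm = cohort$arm)
  if (covariate_adjusted) {
    df <- cbind(df, cohort[covariates])
    w <- if (inherits(weights, "weight_set")) .stopf(
      "the adjusted variant enters covariates instead of balancing weights")
    else if (is.null(weights)) rep(1, nrow(df)) else weights
    df$w <- w
    f <- stats::as.formula(paste("survival::Surv(time, status) ~ arm +",
                                 paste(covariates, collapse = " + ")))
    fit <- survival::coxph(f, data = df, weights = w, ties = "efron",
                           robust = TRUE)
  } else {
    w <- if (inherits(weights, "weight_set")) weights$weights
         else if (is.null(weights)) rep(1, nrow(df)) else weights
    df$w <- w
    fit <- survival::coxph(survival::Surv(time, status) ~ arm, data = df,
                           weights = w, ties = "efron", robust = TRUE)
  }
  cf <- stats::coef(fit)
  ak <- paste0("arm", levels(cohort$arm)[-1])
  se <- sqrt(diag(fit$var))[match(ak, names(cf))]
  hr <- exp(-cf[ak])
  names(hr) <- names(se) <- paste0(levels(cohort$arm)[1], "_vs_",
                                   levels(cohort$arm)[-1])
  list(hr = hr, se_log_hr = se, fit = fit)
}

#' Wald test of effect modification
#'
#' Compares confounder-weighted Cox models with and without arm-by-modifier
#' product terms via a Wald chi-square on the interaction coefficient block,
#' using the robust covariance. Age and starting dose enter as continuous
#' modifiers; categorical modifiers as factors.
#'
#' @param cohort Cohort with follow-up and complete modifier.
#' @param weights `weight_set` or numeric weights.
#' @param modifier One of age, sex, ethnicity, smi_diagnosis, starting_dose.
#' @param estimand,outcome As elsewhere.
#' @return List with the chi-square statistic, degrees of freedom, p-value.
#' @export
wald_interaction_test <- function(cohort, weights, modifier,
                                  estimand = "itt", outcome = "mace") {
  x <- cohort[[modifier]]
  if (length(unique(x[!is.na(x)])) < 2) {
    .stopf("modifier '%s' is constant: test undefined", modifier)
  }
  term <- .outcome_terminal(cohort, estimand, outcome)
  day <- cohort$itt_terminal_day
  day <- ifelse(is.na(day), (term$term - 0.5) * DAYS_PER_MONTH, day)
  day <- pmin(day, term$term * DAYS_PER_MONTH)
  w <- if (inherits(weights, "weight_set")) weights$weights else weights
  df <- data.frame(time = pmax(day, 0.5), status = as.integer(term$event),
                   arm = cohort$arm, mod = x, w = w)
  fit <- survival::coxph(survival::Surv(time, status) ~ arm * mod, data = df,
                         weights = w, ties = "efron", robust = TRUE)
  cf <- stats::coef(fit)
  ix <- grep(":", names(cf))
  b <- cf[ix]
  V <- fit$var[ix, ix, drop = FALSE]
  stat <- drop(t(b) %*% solve(V, b))
  list(statistic = stat, df = length(b),
       p_value = stats::pchisq(stat, length(b), lower.tail = FALSE))
}
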