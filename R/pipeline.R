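# End-to-end emulation: cohort build, imputation, weighting with balance
# checks, discrete-time outcome models, and MI + stratified-bootstrap
# inference, for the intention-to-treat and per-protocol estimands and the
# sensitivity grid.

#' Analysis plan
#'
#' One fully specified analysis of the emulated trial. Defaults equal the
#' primary analysis choices: intention-to-treat, generalised overlap
#' weighting, composite MACE over 60 months, 25 imputations, 500 bootstrap
#' samples per imputation, balance threshold 0.10.
#'
#' @param estimand `"itt"` or `"pp"`.
#' @param weighting `"overlap"`, `"iptw"`, or `"none"` (naive, diagnostics
#'   only).
#' @param outcome Composite `"mace"` or a component (`"mi"`, `"stroke"`,
#'   `"cv_death"`); secondary outcomes are not evaluated per-protocol.
#' @param horizons Months at which risks and contrasts are read (from the one
#'   fitted model).
#' @param censor_weighting `"none"`, `"baseline"`, or
#'   `"baseline_plus_timevarying"`; requires the per-protocol estimand.
#' @param censor_covariates Baseline covariates entering the
#'   censoring-model denominator.
#' @param eligibility `"primary"` or `"inclusive"` (SMI diagnosis at any
#'   time).
#' @param missing `"mice"` or `"complete_case"`.
#' @param m Imputed datasets.
#' @param samples_per_imputation Bootstrap draws per imputation.
#' @param mice_iterations Chained-equation cycles per imputed dataset.
#' @param subgroups Modifiers for effect-modification Wald tests.
#' @param include_hr Report discrete-time hazard ratios from the
#'   no-interaction pooled logistic model.
#' @param include_cox Also bootstrap the weighted Cox hazard ratio.
#' @param time_interaction Arm-by-time products in the hazard model.
#' @param balance_threshold Mean standardised-difference threshold.
#' @param balance_covariates Covariates the balance gate assesses (the
#'   pre-specified confounder set).
#' @param seed Master seed for imputation and bootstrap.
#' @return An object of class `analysis_plan`.
#' @export
analysis_plan <- function(estimand = c("itt", "pp"),
                          weighting = c("overlap", "iptw", "none"),
                          outcome = c("mace", "mi", "stroke", "cv_death"),
                          horizons = c(60, 6),
                          censor_weighting = c("none", "baseline",
                                               "baseline_plus_timevarying"),
                          censor_covariates = covariate_names(),
                          eligibility = c("primary", "inclusive"),
                          missing = c("mice", "complete_case"),
                          m = 25, samples_per_imputation = 500,
                          mice_iterations = 10,
                          subgroups = NULL, include_hr = TRUE,
                          include_cox = FALSE,
                          time_interaction = TRUE,
                          balance_threshold = 0.10,
                          balance_covariates = covariate_names(),
                          seed = 1L) {
  plan <- list(estimand = match.arg(estimand),
               weighting = match.arg(weighting),
               outcome = match.arg(outcome),
               horizons = horizons,
               censor_weighting = match.arg(censor_weighting),
               censor_covariates = censor_covariates,
               eligibility = match.arg(eligibility),
               missing = match.arg(missing),
               m = as.integer(m), mice_iterations = as.integer(mice_iterations),
               include_hr = include_hr,
               samples_per_imputation = as.integer(samples_per_imputation),
               subgroups = subgroups, include_cox = include_cox,
               time_interaction = time_interaction,
               balance_threshold = balance_threshold,
               balance_covariates = balance_covariates,
               seed = as.integer(seed))
  if (plan$estimand == "pp" && plan$outcome != "mace") {
    .stopf("secondary outcomes are not evaluated per-protocol %s",
           "(low absolute event numbers)")
  }
  if (plan$censor_weighting != "none" && plan$estimand != "pp") {
    .stopf("censoring weights require the per-protocol estimand")
  }
  structure(plan, class = "analysis_plan")
}

# Greedy balance-driven design improvement: while any mean |d| exceeds the
# threshold, add the candidate term that most reduces the worst imbalance.
.improve_design <- function(cohort, design, weighting, threshold,
                            covariates = covariate_names()) {
  worst <- function(f) {
    model <- fit_propensity(cohort, f)
    ws <- if (weighting == "iptw") iptw_weights(model, cohort$arm)
          else overlap_weights(model, cohort$arm)
    max(vapply(levels(cohort$arm)[-1], function(cmp) {
      max(abs(standardized_differences(
        cohort, ws, c(levels(cohort$arm)[1], cmp),
        covariates = covariates)$d))
    }, numeric(1)))
  }
  f <- design$formula
  added <- character(0)
  cand <- design$candidate_terms
  cur <- worst(f)
  while (cur > threshold && length(cand)) {
    trials <- vapply(cand, function(tm) {
      fr <- stats::update(f, paste("~ . +", tm))
      tryCatch(worst(fr), error = function(e) Inf)
    }, numeric(1))
    if (min(trials) >= cur) break
    best <- names(which.min(trials))
    f <- stats::update(f, paste("~ . +", best))
    added <- c(added, best)
    cand <- setdiff(cand, best)
    cur <- min(trials)
  }
  list(formula = f, added = added, worst = cur)
}

# Row-wise lagged cumulative product of censoring ratios into an n x horizon
# weight matrix (weight is 1 in month 1, before any censoring opportunity).
.ipcw_matrix <- function(ratio_long, idx, month, n, horizon, trim_percentile) {
  R <- matrix(1, n, horizon)
  R[cbind(idx, month)] <- ratio_long
  W <- matrix(1, n, horizon)
  acc <- rep(1, n)
  for (t in 2:horizon) {
    acc <- acc * R[, t - 1L]
    W[, t] <- acc
  }
  if (!is.na(trim_percentile)) {
    used <- W[cbind(idx, month)]
    cap <- stats::quantile(used, trim_percentile / 100, names = FALSE)
    W <- pmin(W, cap)
    attr(W, "trim_value") <- cap
  }
  W
}

# Weighted logistic IRLS on aggregated cells with warm starts (zero-mass
# cells carry zero weight and drop out of the estimating equations).
.fit_logistic_cells <- function(X, y, w, start = NULL, tol = 1e-9,
                                maxit = 30L) {
  b <- if (is.null(start)) {
    c(stats::qlogis(max(sum(w * y) / sum(w), 1e-6)),
      rep(0, ncol(X) - 1L))
  } else start
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    g <- crossprod(X, w * (y - mu))
    if (max(abs(g)) < tol * (1 + sum(w))) break
    Wd <- w * mu * (1 - mu)
    H <- crossprod(X, Wd * X)
    step <- tryCatch(solve(H, g), error = function(e)
      qr.solve(H + diag(1e-10, ncol(X)), g))
    b <- b + drop(step)
  }
  b
}

# The bootstrap estimator: propensity -> weights -> (censor weights) ->
# pooled logistic -> risks and contrasts, with caches (design matrices, warm
# starts) rebuilt on each full-data call and reused across that dataset's
# bootstrap draws.
.make_estimator <- function(plan, ps_formula, horizon = HORIZON_MONTHS,
                            comorbidity = NULL) {
  cache <- new.env(parent = emptyenv())
  function(cohort, counts) {
    n <- nrow(cohort)
    full <- is.null(counts)
    if (full) {
      cache$X <- stats::model.matrix(ps_formula, cohort)
      cache$arm <- cohort$arm
      cache$arm_int <- as.integer(cohort$arm)
      tm <- .outcome_terminal(cohort, plan$estimand, plan$outcome, horizon)
      cache$T_i <- tm$term
      cache$event <- tm$event
      cache$start <- NULL
      arms <- levels(cohort$arm)
      grid_arm <- factor(rep(arms, each = horizon), levels = arms)
      grid_month <- rep(seq_len(horizon), length(arms))
      cache$Xc <- .hazard_design(grid_arm, grid_month, arms,
                                 plan$time_interaction, "linear")
      cache$Xc_hr <- .hazard_design(grid_arm, grid_month, arms, FALSE,
                                    "linear")
      cache$arm_rows <- lapply(seq_along(arms), function(k)
        (k - 1L) * horizon + seq_len(horizon))
      cache$beta_cells <- NULL
      cache$beta_hr <- NULL
      if (plan$censor_weighting != "none") {
        spec <- censor_model_spec(
          covariate_set = if (plan$censor_weighting == "baseline")
            "baseline_only" else plan$censor_weighting,
          covariates = plan$censor_covariates, include_admin = TRUE)
        cm <- fit_censoring_model(cohort, spec, comorbidity, horizon)
        cache$cm <- cm
        cache$Xnum <- stats::model.matrix(cm$num_fit)
        cache$Xden <- stats::model.matrix(cm$den_fit)
        cache$ynum <- cm$num_fit$y
        cache$num_start <- stats::coef(cm$num_fit)
        cache$den_start <- stats::coef(cm$den_fit)
        cache$trim <- spec$trim_percentile
      }
    }
    w_freq <- if (full) rep(1, n) else counts
    arms <- levels(cache$arm)
    est <- c()
    if (plan$weighting == "none") {
      u <- w_freq
    } else {
      fit <- .fit_multinom(cache$X, cache$arm_int, nlevels(cache$arm),
                           w = w_freq, start = cache$start,
                           tol = if (full) 1e-6 else 1e-2, maxit = 100L)
      if (full) cache$start <- fit$coefficients
      P <- fit$fitted
      own <- P[cbind(seq_len(n), cache$arm_int)]
      if (any(own <= 0)) .stopf("zero fitted propensity")
      if (plan$weighting == "overlap") {
        wb <- (1 / own) / rowSums(1 / P)
      } else {
        prev <- as.numeric(rowsum(w_freq, cache$arm_int)) / sum(w_freq)
        wb <- prev[cache$arm_int] / own
        wb <- pmin(wb, stats::quantile(rep(wb, w_freq), 0.99, names = FALSE))
      }
      u <- w_freq * wb
    }
    wm <- NULL
    if (plan$censor_weighting != "none") {
      cm <- cache$cm
      wlong <- w_freq[cm$patient]
      refit <- function(X, y, start) {
        suppressWarnings(stats::glm.fit(X, y, weights = wlong,
                                        family = stats::binomial(),
                                        start = start))$fitted.values
      }
      p_num <- refit(cache$Xnum, cache$ynum, cache$num_start)
      p_den <- refit(cache$Xden, cache$ynum, cache$den_start)
      ratio <- (1 - p_num) / (1 - p_den)
      if (any(!is.finite(ratio))) .stopf("censoring-probability underflow")
      W <- .ipcw_matrix(ratio, cm$patient, cm$month, n, horizon, cache$trim)
      wm <- W * u
    }
    # Aggregate to the fixed (arm x month) grid.
    atrisk <- numeric(length(arms) * horizon)
    events <- numeric(length(arms) * horizon)
    for (k in seq_along(arms)) {
      rows <- which(cache$arm_int == k)
      Tk <- cache$T_i[rows]
      if (is.null(wm)) {
        wk <- u[rows]
        byT <- numeric(horizon)
        tt <- rowsum(wk, Tk)
        byT[as.integer(rownames(tt))] <- tt
        ar <- rev(cumsum(rev(byT)))
        ev <- numeric(horizon)
        ee <- rows[cache$event[rows]]
        if (length(ee)) {
          s <- rowsum(u[ee], cache$T_i[ee])
          ev[as.integer(rownames(s))] <- s
        }
      } else {
        Wk <- wm[rows, , drop = FALSE]
        Wk[outer(Tk, seq_len(horizon), `<`)] <- 0
        ar <- colSums(Wk)
        ev <- numeric(horizon)
        ee <- rows[cache$event[rows]]
        if (length(ee)) {
          s <- rowsum(wm[cbind(ee, cache$T_i[ee])], cache$T_i[ee])
          ev[as.integer(rownames(s))] <- s
        }
      }
      gi <- cache$arm_rows[[k]]
      atrisk[gi] <- ar
      events[gi] <- ev
    }
    if (sum(events) <= 0) .stopf("no events in this draw")
    y <- ifelse(atrisk > 0, events / pmax(atrisk, 1e-300), 0)
    beta <- .fit_logistic_cells(cache$Xc, y, atrisk, start = cache$beta_cells)
    if (full) cache$beta_cells <- beta
    for (k in seq_along(arms)) {
      h_k <- stats::plogis(drop(cache$Xc[cache$arm_rows[[k]], ,
                                         drop = FALSE] %*% beta))
      R <- 1 - cumprod(1 - h_k)
      a <- arms[k]
      for (h in plan$horizons) {
        est[sprintf("risk_%s_%dm", a, h)] <- R[h]
      }
    }
    for (h in plan$horizons) {
      r_ref <- est[sprintf("risk_%s_%dm", arms[1], h)]
      for (cmp in arms[-1]) {
        r_c <- est[sprintf("risk_%s_%dm", cmp, h)]
        est[sprintf("rd_per_1000_%s_%dm", cmp, h)] <- 1000 * (r_ref - r_c)
        est[sprintf("rr_%s_%dm", cmp, h)] <-
          if (r_c == 0) NA_real_ else r_ref / r_c
      }
    }
    if (plan$include_hr) {
      beta_hr <- .fit_logistic_cells(cache$Xc_hr, y, atrisk,
                                     start = cache$beta_hr)
      if (full) cache$beta_hr <- beta_hr
      bk <- beta_hr[match(paste0("arm_", arms[-1]), colnames(cache$Xc_hr))]
      hr <- exp(-bk)
      names(hr) <- sprintf("hr_plr_%s", arms[-1])
      est <- c(est, hr)
    }
    if (plan$include_cox) {
      cox <- if (plan$weighting == "none") {
        # naive/adjusted cell: baseline covariates instead of balancing
        # weights; resampling counts still enter as case weights
        fit_cox(cohort, weights = w_freq, estimand = plan$estimand,
                outcome = plan$outcome, covariate_adjusted = TRUE)
      } else {
        fit_cox(cohort, weights = u, estimand = plan$estimand,
                outcome = plan$outcome)
      }
      hc <- cox$hr
      names(hc) <- sprintf("hr_cox_%s", arms[-1])
      est <- c(est, hc)
    }
    est
  }
}

#' Run one emulated analysis end to end
#'
#' Executes build -> impute -> weight -> balance check -> fit -> bootstrap ->
#' pool for the supplied raw tables (or simulation configuration) and plan.
#' Any post-weighting mean absolute standardised difference above the
#' threshold aborts the causal contrast with a balance report (no
#' doubly-robust fallback is implemented).
#'
#' @param tables A `mace_raw_tables` object or a [sim_config()] (generated,
#'   with missingness applied, on the fly).
#' @param plan An [analysis_plan()].
#' @param ps_design_spec A [ps_design()].
#' @return An `emulation_result`: tidy `estimates` (measure, point, CI,
#'   draws), per-arm `risk_curves`, the mean `balance` table, the eligibility
#'   `flow`, subgroup tests, and a reproducibility `manifest`.
#' @export
run_emulation <- function(tables, plan = analysis_plan(),
                          ps_design_spec = ps_design()) {
  if (inherits(tables, "mace_sim_config")) {
    cfg <- tables
    tables <- apply_missingness(generate_cohort(cfg), cfg)
  }
  crit <- eligibility_criteria(inclusive_smi = plan$eligibility == "inclusive")
  cohort <- apply_eligibility(tables, crit)
  if (!nrow(cohort)) .stopf("no eligible patients [stage: eligibility]")
  cohort <- derive_outcomes(cohort, tables$episodes, tables$deaths)
  if (plan$estimand == "pp") {
    cohort <- derive_per_protocol(cohort, tables$prescriptions,
                                  tables$adverse_reaction_codes,
                                  tables$patients)
  }
  flow <- attr(cohort, "flow")

  datasets <- if (plan$missing == "mice") {
    mice_impute(cohort, imputation_config(
      m = plan$m, n_iterations = plan$mice_iterations,
      seed = .substream_seed(plan$seed, "mice")))
  } else {
    list(complete_case(cohort))
  }

  comorbidity <- NULL
  if (plan$censor_weighting == "baseline_plus_timevarying") {
    comorbidity <- comorbidity_counts(cohort, tables$episodes)
  }

  # Balance gate (skipped for naive runs): greedy candidate-term additions on
  # the first completed dataset, then the mean standardised differences
  # across imputations must all sit at or below the threshold.
  ps_formula <- ps_design_spec$formula
  balance <- NULL
  if (plan$weighting != "none") {
    imp <- .improve_design(datasets[[1]], ps_design_spec, plan$weighting,
                           plan$balance_threshold, plan$balance_covariates)
    ps_formula <- imp$formula
    arms <- levels(cohort$arm)
    acc <- NULL
    for (d in datasets) {
      model <- fit_propensity(d, ps_formula)
      ws <- if (plan$weighting == "iptw") iptw_weights(model, d$arm)
            else overlap_weights(model, d$arm)
      for (cmp in arms[-1]) {
        sd_d <- standardized_differences(d, ws, c(arms[1], cmp),
                                         covariates = plan$balance_covariates)
        sd_d$pair <- paste(arms[1], "vs", cmp)
        acc <- rbind(acc, sd_d)
      }
    }
    acc$level[is.na(acc$level)] <- ""
    balance <- stats::aggregate(d ~ covariate + level + pair, data = acc,
                                FUN = mean, na.action = NULL)
    names(balance)[names(balance) == "d"] <- "mean_d"
    balance$flagged <- abs(balance$mean_d) > plan$balance_threshold
    if (any(balance$flagged)) {
      cond <- structure(class = c("macetrial_balance_error", "error",
                                  "condition"),
                        list(message = paste(
                          "covariate imbalance persists after weighting",
                          "(no doubly-robust fallback is implemented):",
                          "causal contrast aborted"),
                          call = sys.call(), balance = balance))
      stop(cond)
    }
  }

  estimator <- .make_estimator(plan, ps_formula, comorbidity = comorbidity)
  bplan <- bootstrap_plan(plan$samples_per_imputation,
                          seed = .substream_seed(plan$seed, "bootstrap"))
  boot <- bootstrap_pipeline(datasets, bplan, estimator)

  measures <- colnames(boot$points)
  est <- data.frame(measure = measures, point = NA_real_, lower = NA_real_,
                    upper = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_along(measures)) {
    logs <- grepl("^(rr|hr)_", measures[j])
    pt <- rubin_pool(boot$points[, j], log_scale = logs)
    ci <- tryCatch(bca_interval(boot$draws[, j], pt,
                                jackknife = boot$points[, j]),
                   error = function(e) c(NA_real_, NA_real_))
    est$point[j] <- pt
    est$lower[j] <- ci[1]
    est$upper[j] <- ci[2]
  }

  # Risk curves from the first completed dataset's full fit (display only;
  # fitted through the same aggregated sufficient statistics).
  d1 <- datasets[[1]]
  ws1 <- NULL
  if (plan$weighting != "none") {
    model1 <- fit_propensity(d1, ps_formula)
    ws1 <- if (plan$weighting == "iptw") iptw_weights(model1, d1$arm)
           else overlap_weights(model1, d1$arm)
  }
  tm1 <- .outcome_terminal(d1, plan$estimand, plan$outcome)
  cells1 <- .aggregate_cells(tm1$term, tm1$event, d1$arm,
                             if (is.null(ws1)) rep(1, nrow(d1))
                             else ws1$weights)
  hz1 <- fit_pooled_logistic(cells1, time_interaction = plan$time_interaction)
  curves <- do.call(rbind, lapply(levels(cohort$arm), function(a)
    predict_risk_curve(hz1, a)))
  ess <- if (is.null(ws1)) NULL else effective_sample_size(ws1)

  subgroup_tests <- NULL
  if (length(plan$subgroups)) {
    subgroup_tests <- do.call(rbind, lapply(plan$subgroups, function(mod) {
      p <- vapply(datasets, function(d) {
        model <- fit_propensity(d, ps_formula)
        ws <- if (plan$weighting == "iptw") iptw_weights(model, d$arm)
              else overlap_weights(model, d$arm)
        wald_interaction_test(d, ws, mod, plan$estimand,
                              plan$outcome)$p_value
      }, numeric(1))
      data.frame(modifier = mod, p_value = stats::median(p))
    }))
  }

  structure(list(estimates = est, risk_curves = curves, balance = balance,
                 flow = flow, ess = ess, subgroup_tests = subgroup_tests,
                 boot = boot, plan = plan, ps_formula = ps_formula,
                 manifest = list(
                   plan_hash = .config_hash(unclass(plan)),
                   seed = plan$seed, n_cohort = nrow(cohort),
                   m = length(datasets),
                   samples_per_imputation = plan$samples_per_imputation,
                   package_version = as.character(
                     utils::packageVersion("macetrial")),
                   r_version = R.version.string)),
            class = "emulation_result")
}

#' @export
print.emulation_result <- function(x, ...) {
  cat(sprintf("Emulated trial analysis (%s, %s weighting, outcome %s)\n",
              x$plan$estimand, x$plan$weighting, x$plan$outcome))
  cat(sprintf("  cohort n = %d, m = %d imputations, B = %d draws/imputation\n",
              x$manifest$n_cohort, x$manifest$m,
              x$manifest$samples_per_imputation))
  main <- x$estimates[grepl("^(risk|rd|rr)_", x$estimates$measure) &
                        grepl("60m$", x$estimates$measure), ]
  print(transform(main, point = signif(point, 3), lower = signif(lower, 3),
                  upper = signif(upper, 3)), row.names = FALSE)
  invisible(x)
}

#' Run the sensitivity grid
#'
#' Re-runs the emulation under the pre-specified alternative approaches:
#' intention-to-treat with IPT weighting (pooled logistic and Cox),
#' covariate-adjusted Cox, complete-case analysis, inclusive eligibility, and
#' a naive unweighted cell; per-protocol with overlap weights alone, with
#' baseline and time-varying censoring weights, and with IPT weights.
#' Failures are isolated per cell.
#'
#' @param tables Raw tables (a `mace_raw_tables`).
#' @param base_plan The primary intention-to-treat [analysis_plan()].
#' @param cells Optional subset of cell names to run.
#' @return A forest-plot-ready data frame (analysis x measure with CIs).
#' @export
sensitivity_suite <- function(tables, base_plan = analysis_plan(),
                              cells = NULL) {
  stopifnot(base_plan$estimand == "itt")
  modify <- function(...) {
    args <- list(...)
    p <- unclass(base_plan)
    for (nm in names(args)) p[[nm]] <- args[[nm]]
    do.call(analysis_plan, p[setdiff(names(p), "stratify_by")])
  }
  grid <- list(
    overlap_plr = base_plan,
    iptw_plr = modify(weighting = "iptw"),
    iptw_cox = modify(weighting = "iptw", include_cox = TRUE),
    adjusted_cox = modify(weighting = "none", include_cox = TRUE),
    unweighted_plr = modify(weighting = "none"),
    complete_case = modify(missing = "complete_case"),
    inclusive_eligibility = modify(eligibility = "inclusive"),
    pp_overlap = modify(estimand = "pp"),
    pp_ipcw_baseline = modify(estimand = "pp", censor_weighting = "baseline"),
    pp_ipcw_timevarying = modify(estimand = "pp",
                                 censor_weighting =
                                   "baseline_plus_timevarying"),
    pp_iptw = modify(estimand = "pp", weighting = "iptw"))
  if (!is.null(cells)) grid <- grid[intersect(names(grid), cells)]
  out <- NULL
  for (nm in names(grid)) {
    res <- tryCatch(run_emulation(tables, grid[[nm]]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      out <- rbind(out, data.frame(analysis = nm, measure = NA_character_,
                                   point = NA_real_, lower = NA_real_,
                                   upper = NA_real_,
                                   error = conditionMessage(res)))
    } else {
      e <- res$estimates
      e <- e[grepl("^(rr|rd_per_1000|hr)_", e$measure), ]
      out <- rbind(out, data.frame(analysis = nm, measure = e$measure,
                                   point = e$point, lower = e$lower,
                                   upper = e$upper, error = NA_character_))
    }
  }
  rownames(out) <- NULL
  out
}
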