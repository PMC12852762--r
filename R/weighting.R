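# Multinomial propensity estimation, generalised overlap weights, stabilised
# IPT weights, balance diagnostics, and effective sample sizes.

#' Propensity design specification
#'
#' @param formula Right-hand-side formula over baseline covariates (main
#'   effects of the default schema unless stated).
#' @param candidate_terms Character vector of candidate non-linear /
#'   interaction terms, added greedily by [run_emulation()] while any mean
#'   absolute standardised difference exceeds the balance threshold.
#' @return An object of class `ps_design`.
#' @export
ps_design <- function(formula = ~ age + sex + ethnicity + smi_diagnosis +
                        imd_quintile + diabetes + hypertension + smoking +
                        bmi + prior_antipsychotic + starting_dose,
                      candidate_terms = c("I(age^2)", "I(bmi^2)",
                                          "I(log(starting_dose))",
                                          "age:sex")) {
  structure(list(formula = formula, candidate_terms = candidate_terms),
            class = "ps_design")
}

#' Fit the multinomial propensity model
#'
#' Maximum-likelihood softmax regression of treatment arm on baseline
#' covariates (Newton iterations, convergence when the max absolute score
#' falls below `tol` or after `maxit` iterations). Collinear design columns
#' are dropped with a warning; apparent perfect separation fails with the
#' offending column named.
#'
#' @param cohort Cohort data frame with complete covariates and an `arm`
#'   factor.
#' @param design A [ps_design()] (or a bare RHS formula).
#' @param freq_weights Optional non-negative frequency weights (bootstrap
#'   resampling counts).
#' @param start Optional warm-start coefficient matrix.
#' @param tol,maxit Convergence controls.
#' @return An object of class `propensity_model` with the coefficient matrix
#'   (reference arm constrained to zero) and fitted probabilities `p_ik`.
#' @export
fit_propensity <- function(cohort, design = ps_design(), freq_weights = NULL,
                           start = NULL, tol = 1e-6, maxit = 200L) {
  f <- if (inherits(design, "ps_design")) design$formula else design
  arm <- cohort$arm
  if (!is.factor(arm)) arm <- factor(arm, levels = study_drugs())
  if (anyNA(arm)) .stopf("treatment must be fully observed")
  X <- stats::model.matrix(f, data = cohort)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning(sprintf("dropping collinear design columns: %s",
                    paste(drop_cols, collapse = ", ")))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  K <- nlevels(arm)
  fit <- .fit_multinom(X, as.integer(arm), K, w = freq_weights, start = start,
                       tol = tol, maxit = maxit)
  if (max(abs(fit$coefficients)) > 30) {
    j <- which(abs(fit$coefficients) == max(abs(fit$coefficients)),
               arr.ind = TRUE)[1, 1]
    .stopf("apparent perfect separation on design column '%s'",
           colnames(X)[j])
  }
  probs <- fit$fitted
  colnames(probs) <- levels(arm)
  structure(list(coefficients = fit$coefficients, design_columns = colnames(X),
                 formula = f, fitted = probs, arms = levels(arm),
                 converged = fit$converged, iterations = fit$iterations,
                 gradient_norm = fit$gradient_norm),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("Multinomial propensity model (%d columns, %s)\n",
              length(x$design_columns),
              if (x$converged) sprintf("converged in %d iterations",
                                       x$iterations) else "NOT converged"))
  invisible(x)
}

.weight_set <- function(weights, scheme, arm, stabilised, trim_percentile,
                        trim_value = NA_real_) {
  structure(list(weights = weights, scheme = scheme, arm = arm,
                 stabilised = stabilised, trim_percentile = trim_percentile,
                 trim_value = trim_value,
                 ess = vapply(split(weights, arm), function(w)
                   sum(w)^2 / sum(w^2), numeric(1))),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("%s weights (n = %d%s)\n", x$scheme, length(x$weights),
              if (!is.na(x$trim_percentile))
                sprintf(", trimmed at the %.1fth percentile",
                        x$trim_percentile) else ""))
  cat("  effective sample sizes:\n")
  print(round(x$ess, 1))
  invisible(x)
}

#' Generalised overlap weights
#'
#' For patient i in arm Z_i with propensities p_ik, the normalised
#' generalised overlap weight is the inverse probability of the received
#' treatment divided by the sum of the inverse probabilities of each
#' treatment: w_i = (1 / p_i,Zi) / sum_k (1 / p_ik). The weights are bounded
#' by construction, target the population at clinical equipoise, and for two
#' arms reduce to the opposite-arm propensity.
#'
#' @param model A fitted [fit_propensity()] model.
#' @param arm Factor of received treatments.
#' @return A `weight_set`.
#' @export
overlap_weights <- function(model, arm) {
  P <- model$fitted
  if (any(P <= 0)) .stopf("zero fitted propensity: refit or clip upstream")
  idx <- cbind(seq_len(nrow(P)), as.integer(factor(arm, levels = model$arms)))
  w <- (1 / P[idx]) / rowSums(1 / P)
  .weight_set(w, "overlap", arm, stabilised = FALSE,
              trim_percentile = NA_real_)
}

#' Stabilised inverse-probability-of-treatment weights
#'
#' w_i = Pr(arm = Z_i) / p_i,Zi, stabilised by the marginal arm prevalence
#' and capped (winsorised) at the given percentile of the weight
#' distribution.
#'
#' @param model A fitted [fit_propensity()] model.
#' @param arm Factor of received treatments.
#' @param trim_percentile Percentile at which weights are capped (99 by
#'   default; `NA` for no capping).
#' @return A `weight_set`.
#' @export
iptw_weights <- function(model, arm, trim_percentile = 99) {
  P <- model$fitted
  if (any(P <= 0)) .stopf("zero fitted propensity: refit or clip upstream")
  f <- factor(arm, levels = model$arms)
  prev <- as.numeric(table(f) / length(f))
  idx <- cbind(seq_len(nrow(P)), as.integer(f))
  w <- prev[as.integer(f)] / P[idx]
  trim_value <- NA_real_
  if (!is.na(trim_percentile)) {
    trim_value <- stats::quantile(w, trim_percentile / 100, names = FALSE)
    w <- pmin(w, trim_value)
  }
  .weight_set(w, "iptw", arm, stabilised = TRUE,
              trim_percentile = trim_percentile, trim_value = trim_value)
}

#' Weighted standardised differences
#'
#' Balance diagnostic for one arm pair: for continuous covariates,
#' d = (weighted mean 1 - weighted mean 2) / sqrt((s1^2 + s2^2)/2) with
#' unweighted pooled standard deviations (so weighting moves the numerator
#' only); categorical covariates contribute one per-level prevalence
#' difference on the same scale. |d| > 0.10 flags meaningful imbalance.
#'
#' @param cohort Cohort with complete covariates.
#' @param weights A `weight_set`, bare numeric vector, or `NULL` (unweighted).
#' @param arm_pair Character vector of two arm labels.
#' @param covariates Covariate columns to assess.
#' @param threshold Flagging threshold.
#' @return Data frame with columns covariate, level, d, flagged.
#' @export
standardized_differences <- function(cohort, weights = NULL,
                                     arm_pair = c("aripiprazole", "olanzapine"),
                                     covariates = covariate_names(),
                                     threshold = 0.10) {
  w <- if (inherits(weights, "weight_set")) weights$weights
       else if (is.null(weights)) rep(1, nrow(cohort)) else weights
  g1 <- cohort$arm == arm_pair[1]
  g2 <- cohort$arm == arm_pair[2]
  rows <- list()
  wmean <- function(x, sel) sum(w[sel] * x[sel]) / sum(w[sel])
  sdiff <- function(x) {
    s1 <- stats::var(x[g1]); s2 <- stats::var(x[g2])
    pooled <- sqrt((s1 + s2) / 2)
    if (!is.finite(pooled) || pooled == 0) return(0)
    (wmean(x, g1) - wmean(x, g2)) / pooled
  }
  for (v in covariates) {
    x <- cohort[[v]]
    if (is.numeric(x) || is.logical(x)) {
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = v, level = NA_character_, d = sdiff(as.numeric(x)))
    } else {
      for (lev in levels(factor(x))) {
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = v, level = lev, d = sdiff(as.numeric(x == lev)))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$flagged <- abs(out$d) > threshold
  out
}

#' Kish effective sample size
#'
#' ESS = (sum w)^2 / sum(w^2), per arm: the equal-weight sample size with
#' equivalent precision. Always at most the arm's n, with equality iff the
#' weights are constant within the arm.
#'
#' @param weights A `weight_set` or numeric vector of non-negative weights.
#' @param arm Arm factor (required when `weights` is a bare vector).
#' @return Named numeric vector of per-arm effective sample sizes.
#' @export
effective_sample_size <- function(weights, arm = NULL) {
  if (inherits(weights, "weight_set")) {
    w <- weights$weights
    if (is.null(arm)) arm <- weights$arm
  } else w <- weights
  if (is.null(arm)) arm <- rep("all", length(w))
  sp <- split(w, arm)
  out <- numeric(length(sp))
  names(out) <- names(sp)
  for (a in names(sp)) {
    wi <- sp[[a]]
    if (all(wi == 0)) .stopf("all weights zero within arm '%s'", a)
    out[a] <- sum(wi)^2 / sum(wi^2)
  }
  out
}
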