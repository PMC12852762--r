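# Multiple imputation by chained equations over baseline covariates:
# predictive mean matching for continuous variables, multinomial logistic
# posterior-predictive draws for categorical variables. Deliberately a
# lightweight two-engine implementation so every draw is auditable. The
# outcome enters the predictor matrix as the event indicator and log
# follow-up time (survival-aware imputation convention).

#' Imputation configuration
#'
#' @param m Number of completed datasets (25 in the primary analysis).
#' @param n_iterations Chained-equation cycles per dataset.
#' @param pmm_donors Donor-pool size for predictive mean matching.
#' @param predictors Covariates allowed as predictors (all schema covariates
#'   by default; treatment and outcome summaries are always added).
#' @param seed Seed (each of the m datasets uses an independent substream).
#' @return An object of class `imputation_config`.
#' @export
imputation_config <- function(m = 25, n_iterations = 10, pmm_donors = 5,
                              predictors = covariate_names(), seed = 1L) {
  stopifnot(m >= 2, pmm_donors >= 1, n_iterations >= 1)
  structure(list(m = as.integer(m), n_iterations = as.integer(n_iterations),
                 pmm_donors = as.integer(pmm_donors), predictors = predictors,
                 seed = as.integer(seed)),
            class = "imputation_config")
}

# Predictive mean matching with a Bayesian parameter draw: regress observed y
# on X, draw (sigma, beta) from the approximate posterior, match each missing
# case to the `donors` observed cases with the closest predicted mean, and
# impute an observed value drawn uniformly from that pool.
.pmm_impute <- function(X, y, mis, donors) {
  obs <- !mis
  Xo <- X[obs, , drop = FALSE]
  qr_o <- qr(Xo)
  rank <- qr_o$rank
  cols <- qr_o$pivot[seq_len(rank)]
  Xo <- Xo[, cols, drop = FALSE]
  fit <- stats::lm.fit(Xo, y[obs])
  beta <- fit$coefficients
  res <- fit$residuals
  df <- max(length(res) - rank, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  R <- qr.R(qr(Xo))
  pert <- tryCatch(backsolve(R, stats::rnorm(rank)) * sqrt(sigma2),
                   error = function(e) rep(0, rank))
  beta_dot <- beta + pert
  yhat_obs <- drop(Xo %*% beta)
  Xm <- X[mis, cols, drop = FALSE]
  yhat_mis <- drop(Xm %*% beta_dot)
  ord <- order(yhat_obs)
  yo_sorted <- y[obs][ord]
  yh_sorted <- yhat_obs[ord]
  pos <- findInterval(yhat_mis, yh_sorted)
  n_obs <- length(yh_sorted)
  out <- numeric(length(yhat_mis))
  for (j in seq_along(yhat_mis)) {
    lo <- max(1L, pos[j] - donors)
    hi <- min(n_obs, pos[j] + donors)
    win <- lo:hi
    d <- abs(yh_sorted[win] - yhat_mis[j])
    pool <- win[order(d)][seq_len(min(donors, length(win)))]
    out[j] <- yo_sorted[pool[sample.int(length(pool), 1L)]]
  }
  out
}

# Multinomial posterior-predictive draw for a categorical variable
# (warm-started across chained-equation cycles).
.cat_impute <- function(X, y, mis, warm = NULL, key = NULL) {
  obs <- !mis
  yf <- factor(y[obs])
  K <- nlevels(yf)
  qr_o <- qr(X[obs, , drop = FALSE])
  cols <- sort(qr_o$pivot[seq_len(qr_o$rank)])
  start <- NULL
  if (!is.null(warm) && !is.null(warm[[key]]) &&
        identical(warm[[key]]$cols, cols)) {
    start <- warm[[key]]$coefficients
  }
  fit <- .fit_multinom(X[obs, cols, drop = FALSE], as.integer(yf), K,
                       w = NULL, start = start, tol = 1e-5, maxit = 50L)
  if (!is.null(warm)) {
    warm[[key]] <- list(cols = cols, coefficients = fit$coefficients)
  }
  eta <- X[mis, cols, drop = FALSE] %*% fit$coefficients
  eta <- cbind(0, eta)
  eta <- eta - apply(eta, 1, max)
  P <- exp(eta) / rowSums(exp(eta))
  u <- stats::runif(nrow(P))
  cp <- t(apply(P, 1, cumsum))
  levels(yf)[.first_true(cp >= u)]
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed cohorts. Initial values are sampled from the
#' observed marginal of each variable; each cycle then re-imputes every
#' incomplete variable from a model on all other covariates plus the
#' treatment arm, the event indicator, and log follow-up time (outcome and
#' treatment are required to be fully observed). Continuous variables use
#' predictive mean matching; categorical variables use multinomial logistic
#' draws.
#'
#' @param cohort Cohort with follow-up derived and possibly missing
#'   covariates.
#' @param config An [imputation_config()].
#' @param covariates Schema covariates considered for imputation.
#' @return A list of `m` completed cohorts; chain means per iteration are
#'   attached as `attr(, "chain_means")`.
#' @export
mice_impute <- function(cohort, config = imputation_config(),
                        covariates = covariate_names()) {
  if (anyNA(cohort$arm)) .stopf("treatment must be fully observed")
  incomplete <- covariates[vapply(covariates, function(v)
    anyNA(cohort[[v]]), logical(1))]
  zero_obs <- incomplete[vapply(incomplete, function(v)
    all(is.na(cohort[[v]])), logical(1))]
  if (length(zero_obs)) {
    .stopf("variable(s) with zero observed values: %s",
           paste(zero_obs, collapse = ", "))
  }
  if (!length(incomplete)) {
    return(lapply(seq_len(config$m), function(i) cohort))
  }
  term <- if ("itt_event_month" %in% names(cohort)) {
    .outcome_terminal(cohort, "itt", "mace")
  } else list(term = rep(HORIZON_MONTHS, nrow(cohort)),
              event = rep(FALSE, nrow(cohort)))
  extra <- data.frame(.arm = cohort$arm,
                      .event = as.integer(term$event),
                      .log_time = log(term$term))
  mis_idx <- lapply(incomplete, function(v) which(is.na(cohort[[v]])))
  names(mis_idx) <- incomplete
  chain_means <- list()

  # Incrementally maintained master design: one dummy-column group per
  # predictor, rebuilt only for the variable just re-imputed, so each cycle
  # costs model fits rather than design construction.
  preds <- config$predictors[config$predictors %in% names(cohort)]
  n <- nrow(cohort)
  col_group <- function(x) {
    if (is.numeric(x) || is.logical(x)) {
      matrix(as.numeric(x), ncol = 1)
    } else {
      f <- factor(x)
      m <- matrix(0, n, nlevels(f) - 1L)
      ii <- as.integer(f)
      for (k in 2:nlevels(f)) m[, k - 1L] <- as.numeric(ii == k)
      m
    }
  }
  extra_X <- cbind(col_group(extra$.arm), extra$.event, extra$.log_time)

  impute_one <- function(imp_seed) {
    .with_seed(imp_seed, {
      work <- cohort
      for (v in incomplete) {
        obs_vals <- work[[v]][!is.na(work[[v]])]
        work[[v]][mis_idx[[v]]] <- sample(obs_vals, length(mis_idx[[v]]),
                                          replace = TRUE)
      }
      groups <- lapply(preds, function(v) col_group(work[[v]]))
      names(groups) <- preds
      means <- matrix(NA_real_, config$n_iterations, length(incomplete),
                      dimnames = list(NULL, incomplete))
      warm <- new.env(parent = emptyenv())
      for (it in seq_len(config$n_iterations)) {
        for (v in incomplete) {
          X <- cbind(1, do.call(cbind, groups[setdiff(preds, v)]), extra_X)
          mis <- seq_len(n) %in% mis_idx[[v]]
          if (is.numeric(cohort[[v]])) {
            work[[v]][mis_idx[[v]]] <- .pmm_impute(X, work[[v]], mis,
                                                   config$pmm_donors)
            means[it, v] <- mean(work[[v]][mis_idx[[v]]])
          } else {
            drawn <- .cat_impute(X, as.character(work[[v]]), mis, warm, v)
            lv <- levels(factor(cohort[[v]]))
            work[[v]][mis_idx[[v]]] <- drawn     # character-safe assignment
            means[it, v] <- mean(drawn == lv[1])
          }
          groups[[v]] <- col_group(work[[v]])
        }
      }
      attr(work, "chain_means") <- means
      work
    })
  }
  out <- vector("list", config$m)
  for (i in seq_len(config$m)) {
    out[[i]] <- impute_one(.substream_seed(config$seed, paste0("mice:", i)))
    chain_means[[i]] <- attr(out[[i]], "chain_means")
  }
  attr(out, "chain_means") <- chain_means
  attr(out, "incomplete") <- incomplete
  out
}

#' Complete-case analysis dataset
#'
#' Removes rows with any missing modelled covariate, reporting the count.
#'
#' @param cohort Cohort data frame.
#' @param covariates Covariates considered.
#' @return The complete-case cohort, with `attr(, "n_removed")`.
#' @export
complete_case <- function(cohort, covariates = covariate_names()) {
  present <- covariates[covariates %in% names(cohort)]
  drop <- Reduce(`|`, lapply(present, function(v) is.na(cohort[[v]])))
  if (is.null(drop)) drop <- rep(FALSE, nrow(cohort))
  out <- cohort[!drop, , drop = FALSE]
  if (nrow(out) == 0) warning("no complete cases remain")
  attr(out, "n_removed") <- sum(drop)
  attr(out, "flow") <- attr(cohort, "flow")
  attr(out, "horizon") <- attr(cohort, "horizon")
  out
}
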