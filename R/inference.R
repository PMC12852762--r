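# Combination of multiple imputation and stratified bootstrap into point
# estimates and bias-corrected and accelerated (BCa) confidence intervals.

#' Bootstrap plan
#'
#' @param samples_per_imputation Bootstrap draws per imputed dataset (500 in
#'   the primary analysis; 100 in the reduced mode used for subgroup and
#'   sensitivity analyses).
#' @param seed Seed; draws are deterministic given the seed.
#' @param max_failure_rate Estimator failures tolerated before aborting.
#' @return An object of class `bootstrap_plan`.
#' @export
bootstrap_plan <- function(samples_per_imputation = 500, seed = 1L,
                           max_failure_rate = 0.05) {
  stopifnot(samples_per_imputation >= 1)
  structure(list(samples_per_imputation = as.integer(samples_per_imputation),
                 stratify_by = "arm", seed = as.integer(seed),
                 max_failure_rate = max_failure_rate),
            class = "bootstrap_plan")
}

#' Pool estimates across imputed datasets (Rubin's rules)
#'
#' Arithmetic mean of the per-imputation point estimates; ratio measures
#' (RR, HR) are pooled on the log scale and back-transformed.
#'
#' @param estimates Numeric vector of per-imputation estimates.
#' @param log_scale Pool on the log scale.
#' @return The pooled point estimate.
#' @export
rubin_pool <- function(estimates, log_scale = FALSE) {
  bad <- !is.finite(estimates)
  if (any(bad)) {
    warning(sprintf("excluding %d non-finite estimate(s) from pooling",
                    sum(bad)))
    estimates <- estimates[!bad]
  }
  if (!length(estimates)) return(NA_real_)
  if (log_scale) exp(mean(log(estimates))) else mean(estimates)
}

# Stratified resampling counts: within each arm, n_k draws with replacement,
# represented as per-patient frequency weights (per-arm totals are preserved
# exactly in every draw).
.stratified_counts <- function(arm) {
  n <- length(arm)
  counts <- integer(n)
  for (k in levels(arm)) {
    idx <- which(arm == k)
    draw <- sample(idx, length(idx), replace = TRUE)
    tb <- tabulate(draw, nbins = n)
    counts <- counts + tb
  }
  counts
}

#' Bootstrap the full estimation pipeline across imputed datasets
#'
#' Within each completed dataset, draws patients with replacement stratified
#' by treatment arm and re-runs the supplied estimator -- the full
#' weight-estimation plus outcome-model pipeline, never a refit of the
#' outcome model alone. Draws are pooled across imputations into one
#' distribution. The estimator receives the dataset and a per-patient
#' frequency-weight vector (`NULL` for the full data) and returns a named
#' numeric vector.
#'
#' @param datasets List of completed cohorts (one per imputation).
#' @param plan A [bootstrap_plan()].
#' @param estimator `function(cohort, counts)` returning a named numeric
#'   vector of estimates.
#' @return A `bootstrap_result`: per-imputation full-data estimates
#'   (`points`, m x stats), the pooled draw matrix (`draws`), and the failure
#'   count. Errors in more than `max_failure_rate` of draws abort.
#' @export
bootstrap_pipeline <- function(datasets, plan, estimator) {
  m <- length(datasets)
  B <- plan$samples_per_imputation
  points <- NULL
  draws <- NULL
  failures <- 0L
  for (d in seq_len(m)) {
    data_d <- datasets[[d]]
    pt <- estimator(data_d, NULL)
    if (is.null(points)) {
      points <- matrix(NA_real_, m, length(pt),
                       dimnames = list(NULL, names(pt)))
      draws <- matrix(NA_real_, m * B, length(pt),
                      dimnames = list(NULL, names(pt)))
    }
    points[d, ] <- pt
    arm <- factor(data_d$arm)
    .with_seed(.substream_seed(plan$seed, paste0("boot:", d)), {
      for (b in seq_len(B)) {
        counts <- .stratified_counts(arm)
        est <- tryCatch(estimator(data_d, counts), error = function(e) NULL)
        if (is.null(est)) {
          failures <- failures + 1L
        } else {
          draws[(d - 1L) * B + b, ] <- est
        }
      }
    })
  }
  rate <- failures / (m * B)
  if (rate > plan$max_failure_rate) {
    .stopf("bootstrap failure rate %.1f%% exceeds %.1f%%", 100 * rate,
           100 * plan$max_failure_rate)
  }
  structure(list(points = points, draws = draws, failures = failures,
                 plan = plan), class = "bootstrap_result")
}

#' Bias-corrected and accelerated (BCa) confidence interval
#'
#' z0 is the normal quantile of the fraction of bootstrap draws below the
#' point estimate; the acceleration a comes from a jackknife over the
#' per-imputation estimates (or 0 in bias-corrected-only mode). Bounds are
#' quantiles of the draw distribution at the BCa-adjusted levels.
#'
#' @param draws Bootstrap distribution (finite draws; at least 100).
#' @param point Point estimate (the Rubin-pooled value).
#' @param alpha Two-sided level (0.05 for 95% intervals).
#' @param jackknife Per-imputation estimates for the acceleration (NULL for
#'   a = 0).
#' @return Numeric `c(lower, upper)` with attributes `z0` and `a`; degenerate
#'   distributions collapse to the point with a flag.
#' @export
bca_interval <- function(draws, point, alpha = 0.05, jackknife = NULL) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 100) .stopf("need at least 100 finite draws")
  if (stats::sd(draws) == 0) {
    out <- c(point, point)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  frac <- mean(draws < point)
  frac <- min(max(frac, 1 / (length(draws) + 1)),
              length(draws) / (length(draws) + 1))
  z0 <- stats::qnorm(frac)
  a <- 0
  if (!is.null(jackknife) && length(jackknife) >= 3) {
    jm <- mean(jackknife)
    num <- sum((jm - jackknife)^3)
    den <- 6 * sum((jm - jackknife)^2)^1.5
    if (den > 0) a <- num / den
  }
  zq <- stats::qnorm(c(alpha / 2, 1 - alpha / 2))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  out <- unname(stats::quantile(draws, adj, type = 7))
  attr(out, "z0") <- z0
  attr(out, "a") <- a
  if (point < out[1] || point > out[2]) {
    attr(out, "point_outside") <- TRUE
    warning("BCa interval does not contain the point estimate")
  }
  out
}
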