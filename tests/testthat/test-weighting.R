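# Multinomial propensity model, overlap / IPT weights, balance diagnostics,
# and effective sample sizes.

sim_cohort <- function(n, seed) {
  cfg <- sim_config(n_patients = n, seed = seed, missingness_spec = list())
  tabs <- generate_cohort(cfg)
  derive_outcomes(apply_eligibility(tabs), tabs$episodes, tabs$deaths)
}

test_that("with covariates independent of arm, fitted p_ik are the arm prevalences", {
  set.seed(1)
  n <- 4000
  cohort <- data.frame(
    arm = factor(sample(study_drugs(), n, replace = TRUE,
                        prob = c(0.1, 0.4, 0.27, 0.23)),
                 levels = study_drugs()),
    x = rnorm(n))
  fit <- fit_propensity(cohort, ~ x)
  prev <- as.numeric(table(cohort$arm) / n)
  expect_lt(max(abs(sweep(fit$fitted, 2, prev))), 0.05)
})

test_that("a saturated binary-covariate model reproduces cell frequencies", {
  set.seed(2)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  probs <- rbind(c(0.1, 0.4, 0.3, 0.2), c(0.3, 0.2, 0.2, 0.3))
  arm <- factor(vapply(x, function(xi)
    sample(study_drugs(), 1, prob = probs[xi + 1, ]), character(1)),
    levels = study_drugs())
  cohort <- data.frame(arm = arm, x = x)
  fit <- fit_propensity(cohort, ~ x)
  for (xi in 0:1) {
    cell <- as.numeric(table(arm[x == xi]) / sum(x == xi))
    expect_equal(unname(fit$fitted[match(xi, x), ]), cell, tolerance = 1e-6)
  }
})

test_that("the Newton softmax fit matches nnet::multinom", {
  skip_if_not_installed("nnet")
  cohort <- sim_cohort(4000, 31)
  fit <- fit_propensity(cohort)
  f <- arm ~ age + sex + ethnicity + smi_diagnosis + imd_quintile +
    diabetes + hypertension + smoking + bmi + prior_antipsychotic +
    starting_dose
  nn <- nnet::multinom(f, data = cohort, trace = FALSE, maxit = 500,
                       reltol = 1e-13)
  expect_lt(max(abs(fit$fitted - fitted(nn))), 1e-5)
})

test_that("softmax coefficients are recovered on a large simulation", {
  cfg <- scenario_config("null", 20000, seed = 37)
  tabs <- generate_cohort(cfg)
  cohort <- derive_outcomes(apply_eligibility(tabs), tabs$episodes,
                            tabs$deaths)
  fit <- fit_propensity(cohort, ~ I((age - 55) / 10) + diabetes)
  # generating coefficients, arm k vs aripiprazole
  truth <- cfg$ps_coefficients[-1, c("age10", "diabetes")]
  est <- t(fit$coefficients[-1, ])
  # 3-SE band via the Hessian-free rough bound 3 * sqrt(K/(n p)) per column
  expect_lt(max(abs(est - truth)), 0.15)
})

test_that("overlap weights follow the normalised inverse-probability formula", {
  P2 <- matrix(c(0.5, 0.5), 1)
  model <- structure(list(fitted = P2, arms = c("a", "b")),
                     class = "propensity_model")
  expect_equal(overlap_weights(model, factor("a", c("a", "b")))$weights, 0.5)
  # K = 2: the weight equals the opposite arm's propensity
  model$fitted <- matrix(c(0.8, 0.2), 1)
  expect_equal(overlap_weights(model, factor("a", c("a", "b")))$weights, 0.2)
  # K = 3 hand computation
  model3 <- structure(list(fitted = matrix(c(0.5, 0.25, 0.25), 1),
                           arms = c("a", "b", "c")),
                      class = "propensity_model")
  expect_equal(overlap_weights(model3, factor("a", c("a", "b", "c")))$weights,
               (1 / 0.5) / (1 / 0.5 + 1 / 0.25 + 1 / 0.25))
  # zero propensity fails loudly
  model3$fitted <- matrix(c(0, 0.5, 0.5), 1)
  expect_error(overlap_weights(model3, factor("a", c("a", "b", "c"))),
               "zero")
})

test_that("K = 2 algebraic identity holds for random propensities", {
  set.seed(11)
  p <- runif(10000, 0.01, 0.99)
  model <- structure(list(fitted = cbind(p, 1 - p), arms = c("a", "b")),
                     class = "propensity_model")
  arm <- factor(ifelse(runif(10000) < 0.5, "a", "b"), c("a", "b"))
  w <- overlap_weights(model, arm)$weights
  opposite <- ifelse(arm == "a", 1 - p, p)
  expect_lt(max(abs(w - opposite)), 1e-12)
  # invariance to rescaling all inverse probabilities
  w2 <- (3 / p) / (3 / p + 3 / (1 - p))
  expect_lt(max(abs(w[arm == "a"] - w2[arm == "a"])), 1e-12)
})

test_that("stabilised IPT weights: identity, capping, and boundedness", {
  set.seed(3)
  n <- 1000
  arm <- factor(sample(study_drugs(), n, TRUE, c(0.1, 0.4, 0.3, 0.2)),
                levels = study_drugs())
  prev <- as.numeric(table(arm) / n)
  P <- matrix(prev, n, 4, byrow = TRUE)
  model <- structure(list(fitted = P, arms = study_drugs()),
                     class = "propensity_model")
  ws <- iptw_weights(model, arm)
  expect_equal(ws$weights, rep(1, n))                  # randomised: all 1
  # capping mechanics
  w <- c(1, 1, 1, 1, 100)
  expect_equal(pmin(w, quantile(w, 0.8)), c(1, 1, 1, 1, quantile(w, 0.8,
                                                                 names = FALSE)))
  # strong confounding: IPTW exceeds the bounded overlap weights
  cohort <- sim_cohort(4000, 41)
  fit <- fit_propensity(cohort)
  ov <- overlap_weights(fit, cohort$arm)
  ip <- iptw_weights(fit, cohort$arm, trim_percentile = NA)
  expect_gt(max(ip$weights), max(ov$weights))
  expect_lt(max(ov$weights), 1)
})

test_that("standardised differences: closed forms and weighting behaviour", {
  cohort <- data.frame(
    arm = factor(rep(c("aripiprazole", "olanzapine"), each = 200),
                 levels = study_drugs()),
    x = c(rnorm(200, 0, 1), rnorm(200, 1, 1)))
  d <- standardized_differences(cohort, NULL,
                                c("aripiprazole", "olanzapine"),
                                covariates = "x")
  s1 <- sd(cohort$x[1:200]); s2 <- sd(cohort$x[201:400])
  manual <- (mean(cohort$x[1:200]) - mean(cohort$x[201:400])) /
    sqrt((s1^2 + s2^2) / 2)
  expect_equal(d$d, manual)
  # identical arms give zero
  cohort$x <- rep(rnorm(200), 2)
  d0 <- standardized_differences(cohort, NULL,
                                 c("aripiprazole", "olanzapine"),
                                 covariates = "x")
  expect_equal(d0$d, 0)
  # zero variance in both arms is defined as 0
  cohort$x <- 1
  expect_equal(standardized_differences(cohort, NULL,
                                        c("aripiprazole", "olanzapine"),
                                        covariates = "x")$d, 0)
})

test_that("overlap weighting balances a correctly specified model", {
  cohort <- sim_cohort(8000, 43)
  fit <- fit_propensity(cohort)
  ws <- overlap_weights(fit, cohort$arm)
  for (cmp in study_drugs()[-1]) {
    d <- standardized_differences(cohort, ws, c("aripiprazole", cmp))
    expect_true(all(abs(d$d) <= 0.10))
  }
  # overlap-weighted covariate means agree across arms (parameter recovery)
  for (v in c("age", "bmi")) {
    wm <- vapply(study_drugs(), function(a) {
      sel <- cohort$arm == a
      sum(ws$weights[sel] * cohort[[v]][sel]) / sum(ws$weights[sel])
    }, numeric(1))
    expect_lt(diff(range(wm)), 3 * sd(cohort[[v]]) / sqrt(min(ws$ess)))
  }
})

test_that("Kish effective sample sizes behave as stated", {
  expect_equal(unname(effective_sample_size(rep(2, 100))), 100)
  expect_equal(unname(effective_sample_size(c(1, 0))), 1)
  expect_equal(unname(effective_sample_size(c(2, 1, 1))), 16 / 6)
  expect_error(effective_sample_size(c(0, 0), factor(c("a", "a"))), "arm 'a'")
  # ESS <= n with equality iff constant weights
  set.seed(5)
  w <- rexp(500)
  expect_lt(unname(effective_sample_size(w)), 500)
})

test_that("collinear design columns are dropped with a warning", {
  cohort <- sim_cohort(1000, 47)
  cohort$age2 <- cohort$age
  expect_warning(fit <- fit_propensity(cohort, ~ age + age2), "collinear")
  expect_true(fit$converged)
})
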