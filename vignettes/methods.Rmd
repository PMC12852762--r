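---
title: "Methods: emulating a four-arm antipsychotic trial for cardiovascular risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emulating a four-arm antipsychotic trial for cardiovascular risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macetrial)
```

# The question and the estimands

People living with severe mental illness (schizophrenia, bipolar disorder,
other non-organic psychoses) carry a markedly elevated cardiovascular risk,
and the second-generation antipsychotics they are most often prescribed —
aripiprazole, olanzapine, quetiapine, risperidone — differ in their
cardiometabolic side-effect profiles. `macetrial` implements, as a tested and
reusable pipeline, the observational emulation of the pragmatic trial one
would like to run: eligible patients are "randomised" at their first
antipsychotic prescription (the index date) to one of the four monotherapy
strategies and followed for five years for major adverse cardiovascular
events (MACE): hospitalised non-fatal myocardial infarction or stroke, or
cardiovascular death.

Two estimands are supported:

* **Intention-to-treat (observational analogue):** the effect of *initiating*
  a strategy, analysed by the initiated drug regardless of later switching,
  addition, or discontinuation.
* **Per-protocol:** the effect of initiating *and continuing* the strategy.
  Follow-up is artificially censored at the first strategy deviation, and
  inverse-probability-of-censoring weights (IPCW) correct the selection this
  censoring induces. A deviation within 30 days of a recorded adverse
  reaction to the initiated drug is treated as strategy-consistent and does
  not censor.

Because the real linked primary-care/hospital/death-registration data that
motivate this design are access-protected, the package ships a synthetic
linked-cohort generator with *known ground truth*; every stage of the
pipeline is validated against that truth or against closed-form oracles.

# The synthetic cohort generator

`generate_cohort()` simulates the four linked tables (patients,
prescriptions, hospital episodes, death registrations, plus rare
adverse-reaction codes) from a `sim_config()`. Its defaults are the study
conditions used throughout the package's validation:

* **Population.** 20,000 patients aged 40–99 (right-skewed, median ≈ 52),
  57% female, an eleven-variable baseline covariate core (age, sex,
  ethnicity, SMI diagnosis, deprivation quintile, diabetes, hypertension,
  smoking, BMI, prior antipsychotic use, starting dose in olanzapine
  equivalents) with marginals resembling a UK severe mental illness cohort.
  The full 33-covariate schema of a real study is deliberately collapsed to
  this tractable core; the schema is config-extensible beyond it.
* **Assignment.** Multinomial softmax on the covariates. The default
  coefficients encode channelling: older patients toward risperidone and
  quetiapine, metabolically higher-risk patients (diabetes, higher BMI)
  toward aripiprazole, with marginal shares near 9/39/28/25%.
* **Outcome process.** A discrete monthly grid of 60 intervals of
  30.4375 days. Each month alive and event-free, MACE occurs with probability
  `expit(logit(h0(t)) + arm effect + covariate effects)` and otherwise
  non-cardiovascular death with a flat 0.0018/month. The default constant
  baseline `h0 = 4.2e-4`/month together with the covariate effects yields a
  five-year marginal MACE risk of about 5.8% and five-year
  non-cardiovascular mortality near 10%. Events are written to the tables
  with the ICD-10 stems the outcome rules need (I21* for MI, I60*–I64* for
  stroke, a circulatory-chapter underlying cause for cardiovascular death);
  15% of MI/stroke admissions are followed by death within 28 days, some
  with a non-circulatory recorded cause so the 28-day reclassification rule
  has work to do.
* **Adherence.** A geometric time to first strategy deviation
  (switch/addition/discontinuation at 30/20/50%), with per-arm monthly rates
  calibrated so that 38–45% of patients have deviated by five years,
  slightly higher for aripiprazole than quetiapine. About 1% of deviations
  carry an adverse-reaction code within 30 days.
* **Missingness.** Missing-at-random logistic models on fully observed
  fields mask ethnicity (~7%), deprivation (~4%), smoking (~13%,
  age-dependent), BMI (~21%, sex-dependent) and the index dose (~5%). The
  pre-masking table is retained so imputation can be scored against truth.
  Which covariates carry missingness in the motivating study is not public;
  these defaults are stated choices, not inferences.
* **Reproducibility.** Every table and variable draws from its own RNG
  substream derived from the master seed, so regeneration is byte-identical
  and enlarging the cohort never perturbs earlier patients' draws.

`true_marginal_risk()` is the ground-truth oracle: the exact cause-specific
cumulative incidence `1 - prod(1 - h_t)` under "everyone assigned arm a",
averaged over a covariate sample, optionally weighted — which is how the
overlap-population truth is read off. Competing non-cardiovascular death is
treated as censoring, matching the estimand of the hazard models; the
package deliberately does not implement an Aalen–Johansen competing-risk
estimator.

`scenario_config()` freezes four named departures from the defaults used in
validation (a null scenario confounded through age and diabetes only; the
same with a protective log(0.8) aripiprazole effect; an
informative-censoring scenario where diabetes drives both deviation and
hazard; and a rare-event scenario with a true hazard ratio of 0.6). These
are defined once, as study conditions, and the validation suite consumes
them unchanged.

# Cohort construction

`apply_eligibility()` sets the index date at the first oral study-drug
prescription and applies the emulation's criteria sequentially, with a
flow-diagram tally: index inside the 2005–2014 recruitment window, age
40–99 at index, at least 6 months' (183 days') registration, no prior
MI/stroke/dementia, no co-prescribed study antipsychotic at index, no
long-acting injectable in the prior 90 days, no pro-re-nata index
prescription, linkage eligibility, and an SMI diagnosis on record no later
than 30 days after index (the grace window reflects delayed communication
of specialist diagnoses). A sensitivity variant accepts SMI codes recorded
at any time.

"Six months" is operationalised as 183 days for both the registration
lookback and the discontinuation gap: unambiguous and safe under date
arithmetic.

`derive_outcomes()` maps days since index to months via
`floor(days / 30.4375) + 1`. The composite event is the first qualifying
MI/stroke admission or cardiovascular death; a death from any cause within
28 days of an MI/stroke admission reclassifies that event as cardiovascular
death, timed at the admission. Events and censorings falling in the same
month resolve event-first — conservative toward capturing outcomes and the
standard discrete-time convention. Component outcomes censor at component
(not composite) incidence: a non-fatal MI does not end stroke follow-up,
but any death does.

`derive_per_protocol()` censors at the earliest of switch, addition,
discontinuation (183 days after the last prescription of the initiated
drug), deregistration, or the practice's last collection date. A new-drug
prescription while the original is still active (within 183 days of its
last issue) is labelled an addition, afterwards a switch; under monthly
prescribing this labelling almost always reads "addition", which is
immaterial because both censor identically. The adverse-reaction exemption
window is anchored at the new drug's first prescription for
switches/additions and at the last prescription for discontinuations; an
exempted deviation suppresses all downstream strategy censoring for that
patient (treatment change under an adverse reaction is strategy-consistent),
while administrative censoring is never exempted.

# Missing data

`mice_impute()` is a deliberately compact chained-equations implementation
with exactly two engines: predictive mean matching (PMM, Bayesian parameter
draw, five nearest donors) for continuous variables and multinomial-logistic
posterior draws for categorical variables. Each incomplete variable is
cycled `n_iterations` times (default 10); each of the `m` datasets (default
25) runs from an independent substream. The predictor matrix contains all
other covariates plus the treatment arm, the event indicator, and log
follow-up time — the survival-aware imputation convention; the motivating
design does not state its predictor matrix, so this default is documented
and configurable. PMM guarantees imputations in the observed support; chain
means per iteration are retained as the convergence diagnostic.
`complete_case()` provides the corresponding sensitivity dataset.

# Weighting

`fit_propensity()` fits the multinomial (softmax) propensity model by
Newton's method with step halving, converging when the largest score
component falls below 1e-6 (at most 200 iterations). It accepts frequency
weights, which is what makes the bootstrap cheap: a resample is a vector of
per-patient counts, never a copied dataset, and refits warm-start from the
full-data coefficients. The fit is cross-checked against an established
multinomial implementation in the test suite.

`overlap_weights()` implements generalised overlap weighting for four arms:
`w_i = (1 / p_{i,Z_i}) / sum_k (1 / p_{ik})` — the inverse probability of
the received treatment normalised by the sum of inverse probabilities. The
weights are bounded in (0, 1), need no trimming, and target the population
at clinical equipoise. For two arms the weight reduces to the opposite
arm's propensity, an identity the tests exercise exhaustively.
`iptw_weights()` provides the stabilised inverse-probability alternative,
capped (winsorised, preserving sample size) at the 99th percentile.

Balance is assessed with `standardized_differences()`: weighted mean
differences scaled by the *unweighted* pooled standard deviation (so
weighting moves the numerator only and pre/post values are comparable),
per level for categorical covariates, against the 0.10 threshold, averaged
across imputed datasets. `run_emulation()` greedily adds candidate
non-linear terms to the propensity design while any mean |d| exceeds the
threshold; if imbalance persists the causal contrast is aborted with a
balance report — there is no doubly-robust fallback. Kish effective sample
sizes `(Σw)² / Σw²` are reported per arm.

# Outcome models and risk standardisation

Person-months are expanded one row per patient-month at risk
(`expand_person_months()`), and the weighted pooled logistic model
`logit h(t, arm) = α + g(t) + Σ β_k arm_k + Σ γ_k arm_k·t` is fitted by
maximum likelihood. `g(t)` is linear in month by default — the smallest
model consistent with a single treatment-by-time product per arm — with a
natural-spline option (3 df) behind a switch. Confounding is carried
entirely by the weights: the hazard model contains only arm and time, so
fitted hazards are marginal in the weighted population and can be collapsed
exactly onto (arm × month) cells; the implementation aggregates
person-months into these sufficient-statistic cells, which makes each
bootstrap refit a 240-row GLM rather than a million-row one. The test suite
verifies the aggregated path equals the long-data path.

Risks follow by g-formula standardisation,
`R(t) = 1 - prod_{u≤t}(1 - h(u, arm))`, monotone and bounded by
construction (asserted on every fit). Contrasts are the risk difference per
1000 and the risk ratio at 60 months, with 6-month secondary readings taken
from the *same* fitted model at `t = 6`, never a refit. Hazard ratios come
two ways: `exp(β_arm)` from the no-interaction pooled logistic
(`approximate_hr()`, valid when monthly events are rare) and a
continuous-time Cox model with Efron ties and robust standard errors
(`fit_cox()`), on the day scale using exact event days where derived and
mid-month days (`(T - 0.5) × 30.4375`) otherwise. Effect modification is
tested by Wald chi-squares on arm-by-modifier blocks of confounder-weighted
Cox models, age and dose continuous, with the median p-value reported
across imputations.

# Censoring weights for the per-protocol estimand

`fit_censoring_model()` pools person-months and models the monthly
probability of per-protocol censoring: the stabilisation numerator contains
arm and time only; the denominator adds baseline covariates and, in the
extended specification, a monthly cumulative count of distinct comorbidity
categories recorded during follow-up. Deregistration/last-collection
censoring is modelled together with strategy deviations by default (all
require prescription records), with a switch to exclude administrative
reasons. `ipcw()` forms the lagged cumulative product of
numerator-over-denominator remaining-uncensored probabilities — month 1 is
exactly 1, before any censoring opportunity — capped at the 99.5th
percentile, and the weights multiply the treatment weights in the pooled
logistic model. Stabilised weights average about 1 among those at risk, and
in the informative-censoring scenario the naive per-protocol risk is
demonstrably biased low while the weighted estimate recovers the
ground-truth risk; the residual gap after trimming is the familiar
truncation bias and stays within Monte-Carlo error at the validated sizes.

# Inference

Point estimates are pooled across imputations by Rubin's rules — arithmetic
means, log-scale means for ratio measures. Uncertainty comes from a
stratified bootstrap of the *whole* estimation procedure: within each
imputed dataset, patients are resampled with replacement within arm
(per-arm n preserved exactly in every draw), the propensity model, weights,
and outcome model are refitted, and the draws from all imputations are
pooled into one distribution (500 per imputation in the primary
configuration, 12,500 in total; 100 per imputation in the reduced mode used
for replicated checks). Estimator failures are recorded and more than 5%
abort the run.

Confidence intervals are bias-corrected and accelerated (BCa): `z0` is the
normal quantile of the fraction of draws below the Rubin-pooled point, and
the acceleration `a` is a jackknife over the m per-imputation estimates —
an honest, cheap choice for an MI-bootstrap ensemble whose exact
acceleration is not prescribed anywhere; `a = 0` (bias-corrected only) is
available, both recorded in the output. The interval is checked against an
independently coded high-precision reference on fixed draws and against the
`boot` package on a mean statistic.

# Numerical choices and degenerate inputs

* Newton/IRLS fits converge on absolute score tolerances (1e-6 for
  full-data propensity fits, relaxed to 1e-2 for warm-started bootstrap
  refits, which moves estimates by less than 1e-7 — verified in
  development); step halving guards non-concave steps; collinear design
  columns are dropped with a warning; apparent separation fails loudly with
  the offending column named.
* Zero fitted propensities and censoring-probability underflow are hard
  errors, never silent clips.
* Empty prescription tables warn and return an empty cohort; an empty
  cohort propagates as empty person-month tables; a MACE admission before
  index in a built cohort (a prevalent event that leaked through
  eligibility) is a hard error.
* Degenerate bootstrap distributions collapse the CI to the point with a
  flag; intervals failing to contain the point are flagged as estimation
  pathology rather than repaired.

# Problem sizes used in validation

The replicated checks run at sizes chosen to give informative Monte-Carlo
error on a single CPU: parameter-recovery and IPCW-recovery runs at
n = 20,000 with 100 bootstrap draws; the null size check at 200 replicates
of n = 5,000 with m = 5 imputations and 100 draws per imputation (the
compact null scenario confounds through age and diabetes only, masks BMI,
and uses 3 chained-equation cycles — one incomplete continuous variable
mixes fast); cross-method hazard-ratio concordance at n = 20,000. The
acceptance script runs the full default-condition pipeline at n = 20,000
with m = 5 and 100 draws per imputation, the package's reduced-bootstrap
convention.

# What passing tests do and do not show

The generator emulates confounded assignment, discrete-time hazards,
competing death, adherence, administrative structure, and MAR missingness —
but not everything real linked records contain: no coding errors or
vocabulary drift, no duplicate or conflicting records, no
measurement error in covariates, no unmeasured confounding, no
missing-not-at-random mechanisms, no calendar-time trends in prescribing or
event rates, and hazards that do not change after a strategy deviation
(so the generator's intention-to-treat and per-protocol ground truths
coincide by design). Passing this suite therefore demonstrates that the
*estimation machinery* is correct under its stated assumptions — not that
those assumptions hold in any particular real dataset.

# Known limitations

* The switch/addition label is indistinguishable under monthly prescribing
  (both censor identically); only the recorded reason differs.
* The Cox hazard ratios reported alongside the pooled-logistic ones use
  robust standard errors per imputation; their bootstrap CIs are only
  computed when `include_cox` is set, because a Cox refit per draw is the
  single most expensive step.
* IPCW corrects selection on measured covariates only, and percentile
  capping trades a small truncation bias for variance, exactly as in the
  analysis it emulates.
* The balance gate aborts rather than falling back to doubly-robust
  estimation.
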