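# Internal helpers: RNG substreams, the monthly time grid, and evaluation of
# named design terms against a covariate frame.

DAYS_PER_MONTH <- 30.4375
HORIZON_MONTHS <- 60L

#' Study drugs
#'
#' The four oral second-generation antipsychotics compared by the emulation,
#' in canonical order. The first element (aripiprazole) is the reference
#' strategy for all pairwise contrasts.
#'
#' @return Character vector of length 4.
#' @export
study_drugs <- function() {
  c("aripiprazole", "olanzapine", "quetiapine", "risperidone")
}

# Deterministic string hash (Horner scheme mod 2^31 - 1), used to derive one
# independent RNG substream per table/variable from the master seed so that
# enlarging the cohort never perturbs draws already made for earlier patients.
.hash_key <- function(key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  h
}

.substream_seed <- function(seed, key) {
  as.integer((as.numeric(seed) + .hash_key(key)) %% 2147483647)
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.substream <- function(seed, key, expr) {
  .with_seed(.substream_seed(seed, key), expr)
}

#' Map days since index to a month on the discrete follow-up grid
#'
#' Follow-up is discretised into months of 30.4375 days. Day 0 is the index
#' date; a day offset d maps to month floor(d / 30.4375) + 1.
#'
#' @param days Numeric vector of day offsets from the index date (>= 0).
#' @return Integer month indices (1-based, uncapped).
#' @export
month_of_day <- function(days) {
  as.integer(floor(days / DAYS_PER_MONTH) + 1)
}

# Mid-month day offset used when serialising month-grid events to calendar
# dates; round-trips through month_of_day() exactly.
.day_of_month <- function(month) {
  round((month - 0.5) * DAYS_PER_MONTH)
}

# Evaluate a named character vector of R expressions against a data frame,
# returning a numeric design matrix with a leading intercept column.
.eval_terms <- function(terms, data) {
  n <- nrow(data)
  out <- matrix(1, nrow = n, ncol = length(terms) + 1L)
  colnames(out) <- c("(intercept)", names(terms))
  for (j in seq_along(terms)) {
    v <- eval(parse(text = terms[[j]])[[1]], envir = data, enclos = baseenv())
    out[, j + 1L] <- as.numeric(v)
  }
  out
}

# First column index holding TRUE in each row of a logical matrix; ncol(m) + 1
# when a row has none.
.first_true <- function(m) {
  max.col(cbind(m, TRUE), ties.method = "first")
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
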