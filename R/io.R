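# Plain-text interchange: the four linked tables as CSV with ISO-8601 dates
# plus a JSON sidecar carrying the generating configuration and ground-truth
# risks; tidy CSV/JSON writers for analysis outputs.

#' Write synthetic raw tables to CSV
#'
#' Writes `patients.csv`, `prescriptions.csv`, `episodes.csv`, `deaths.csv`,
#' and `adverse_reaction_codes.csv` with ISO-8601 dates, and a
#' `sidecar.json` holding the generating configuration and, when the tables
#' carry a configuration, the ground-truth five-year marginal risks per arm.
#'
#' @param tables A `mace_raw_tables`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_raw_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  cfg <- attr(tables, "config")
  if (!is.null(cfg)) {
    truth <- attr(tables, "truth")
    pop <- .draw_covariates(cfg)
    risks <- vapply(cfg$arms, function(a)
      true_marginal_risk(cfg, a, pop), numeric(1))
    side <- list(config = .serialise_config(cfg),
                 true_marginal_risk_60m = as.list(risks))
    jsonlite::write_json(side, file.path(dir, "sidecar.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

.serialise_config <- function(cfg) {
  out <- unclass(cfg)
  out$recruitment_window <- format(out$recruitment_window)
  out$ps_coefficients <- list(
    rows = rownames(out$ps_coefficients),
    cols = colnames(out$ps_coefficients),
    values = unname(apply(out$ps_coefficients, 1, as.numeric,
                          simplify = FALSE)))
  out
}

#' Read raw tables written by [write_raw_tables()]
#'
#' @param dir Directory holding the CSVs.
#' @return A `mace_raw_tables`.
#' @export
read_raw_tables <- function(dir) {
  nm <- c("patients", "prescriptions", "episodes", "deaths",
          "adverse_reaction_codes")
  out <- lapply(nm, function(x) {
    df <- utils::read.csv(file.path(dir, paste0(x, ".csv")),
                          stringsAsFactors = FALSE)
    for (col in intersect(names(df),
                          c("date", "admission_date", "registration_date",
                            "smi_diagnosis_date", "deregistration_date",
                            "last_collection_date"))) {
      df[[col]] <- as.Date(df[[col]])
    }
    df
  })
  names(out) <- nm
  structure(out, class = "mace_raw_tables")
}

#' Write completed imputation datasets as indexed CSVs
#'
#' Emits `imp_001.csv`, `imp_002.csv`, ... plus an `imputation_config.json`
#' echo when a configuration is supplied.
#'
#' @param datasets List of completed cohorts from [mice_impute()].
#' @param dir Output directory.
#' @param config Optional [imputation_config()] to echo.
#' @return `dir`, invisibly.
#' @export
write_imputations <- function(datasets, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(datasets)) {
    utils::write.csv(datasets[[i]],
                     file.path(dir, sprintf("imp_%03d.csv", i)),
                     row.names = FALSE)
  }
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config),
                         file.path(dir, "imputation_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Write analysis weights keyed by patient and imputation
#'
#' @param weights A `weight_set` or list of them (one per imputation).
#' @param patient_id Patient identifiers matching the weight vectors.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(weights, patient_id, path) {
  if (inherits(weights, "weight_set")) weights <- list(weights)
  rows <- do.call(rbind, lapply(seq_along(weights), function(i) {
    data.frame(imputation = i, patient_id = patient_id,
               scheme = weights[[i]]$scheme,
               weight = weights[[i]]$weights)
  }))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write person-month censoring weights keyed by patient, month, imputation
#'
#' @param ipcw_list A censoring-weight matrix from [ipcw()] or a list of them
#'   (one per imputation).
#' @param censor_models Matching `censor_model` object(s) supplying the
#'   person-month index.
#' @param patient_id Patient identifiers.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ipcw_table <- function(ipcw_list, censor_models, patient_id, path) {
  if (!is.list(ipcw_list)) ipcw_list <- list(ipcw_list)
  if (inherits(censor_models, "censor_model")) {
    censor_models <- list(censor_models)
  }
  rows <- do.call(rbind, lapply(seq_along(ipcw_list), function(i) {
    cm <- censor_models[[i]]
    data.frame(imputation = i, patient_id = patient_id[cm$patient],
               month = cm$month,
               weight = ipcw_list[[i]][cbind(cm$patient, cm$month)])
  }))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

# Tiny polynomial hash of a deparsed object, for run manifests.
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write an analysis results bundle
#'
#' Emits `results.json` (estimates with CIs plus the manifest),
#' `risk_curves.csv`, `balance.csv`, and `flow.json`.
#'
#' @param result An `emulation_result`.
#' @param dir Output directory.
#' @param draws Also persist the full bootstrap draw matrix as
#'   `bootstrap_draws.csv`.
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir, draws = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  est <- result$estimates
  payload <- list(
    plan = unclass(result$plan),
    estimates = est,
    ess = as.list(result$ess),
    manifest = result$manifest)
  jsonlite::write_json(payload, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  utils::write.csv(result$risk_curves, file.path(dir, "risk_curves.csv"),
                   row.names = FALSE)
  if (!is.null(result$balance)) {
    utils::write.csv(result$balance, file.path(dir, "balance.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(as.list(result$flow), file.path(dir, "flow.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (draws) {
    utils::write.csv(as.data.frame(result$boot$draws),
                     file.path(dir, "bootstrap_draws.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
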