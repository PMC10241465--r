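#' Read and write longitudinal eGFR data
#'
#' The on-disk dialect is a UTF-8 CSV with header
#' `subject_id,t_days,egfr`, one row per measurement, times as days (may be
#' fractional). [read_longitudinal()] accepts any delimited file with those
#' three columns (extra columns are ignored), so the estimators can be
#' applied to real cohorts.
#'
#' @param data A data frame with columns `subject_id`, `t_days`, `egfr`.
#' @param path File path.
#' @return `read_longitudinal()` returns a tibble sorted by subject and
#'   time; `write_longitudinal()` returns `path` invisibly.
#' @name longitudinal_io
NULL

#' @rdname longitudinal_io
#' @export
write_longitudinal <- function(data, path) {
  stopifnot(all(c("subject_id", "t_days", "egfr") %in% names(data)))
  readr::write_csv(data[, c("subject_id", "t_days", "egfr")], path)
  invisible(path)
}

#' @rdname longitudinal_io
#' @export
read_longitudinal <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("subject_id", "t_days", "egfr")
  if (!all(need %in% names(out))) {
    stop("file must have columns subject_id, t_days, egfr", call. = FALSE)
  }
  dplyr::arrange(out[, need], .data$subject_id, .data$t_days)
}

#' Write the subject truth table of a simulated cohort
#'
#' Columns `subject_id,b0,b1,beta0_i,beta1_i,true_pdi_day` (plus entry day
#' and visit count).
#'
#' @param cohort A `pdi_cohort` object from [simulate_cohort()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_subject_truth <- function(cohort, path) {
  stopifnot(inherits(cohort, "pdi_cohort"))
  readr::write_csv(cohort$truth, path)
  invisible(path)
}

#' Write / read PDI estimates
#'
#' CSV with columns `subject_id,method,pdi_day,valid`.
#'
#' @param estimates A tibble from [estimate_pdi_lr()] or
#'   [estimate_pdi_lme()] (or both row-bound).
#' @param path File path.
#' @return `read_pdi_estimates()` returns the estimates tibble;
#'   `write_pdi_estimates()` returns `path` invisibly.
#' @name estimates_io
NULL

#' @rdname estimates_io
#' @export
write_pdi_estimates <- function(estimates, path) {
  stopifnot(all(c("subject_id", "method", "pdi_day", "valid") %in%
                  names(estimates)))
  readr::write_csv(estimates, path)
  invisible(path)
}

#' @rdname estimates_io
#' @export
read_pdi_estimates <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a Kaplan-Meier curve as CSV
#'
#' Columns `time_days,survival,n_at_risk`.
#'
#' @param km A `pdi_km` object from [km_estimate()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_km_curve <- function(km, path) {
  stopifnot(inherits(km, "pdi_km"))
  readr::write_csv(
    tibble::tibble(time_days = km$time, survival = km$survival,
                   n_at_risk = km$n_risk),
    path
  )
  invisible(path)
}

#' Write a mixed-model fit summary as JSON
#'
#' Fixed effects, variance components and convergence information of a
#' [fit_lme()] result, as a small JSON document.
#'
#' @param fit A `pdi_lme` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_model_summary <- function(fit, path) {
  stopifnot(inherits(fit, "pdi_lme"))
  obj <- list(
    fixed_effects = list(beta0 = fit$beta0_hat, beta1 = fit$beta1_hat),
    variance_components = list(sigma1 = fit$sigma1_hat,
                               sigma2 = fit$sigma2_hat,
                               rho = fit$rho_hat, sigma_e = fit$sigma_e_hat),
    converged = fit$converged,
    reml_loglik = fit$reml_loglik,
    n_subjects = fit$n_subjects
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
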