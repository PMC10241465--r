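#' Mean absolute deviation between true and estimated PDI times
#'
#' \eqn{\sum_i |t^*_i - \hat t^*_i| / N} over the pairs where the estimate
#' exists and is valid. Invalid or missing estimates are dropped from the
#' average; the number dropped is reported in the `n_dropped` attribute.
#' Negative or beyond-study estimates are retained unmodified — their
#' absolute deviation is still defined.
#'
#' @param truth Numeric vector of true PDI days.
#' @param estimates Numeric vector of estimated PDI days (`NA` = invalid),
#'   same length.
#' @return The mean absolute deviation in days, with attribute `n_dropped`.
#' @examples
#' pdi_mad(c(0, 10), c(5, 5))
#' @export
pdi_mad <- function(truth, estimates) {
  stopifnot(length(truth) == length(estimates))
  ok <- !is.na(truth) & !is.na(estimates)
  if (!any(ok)) stop("no valid (truth, estimate) pairs", call. = FALSE)
  out <- mean(abs(truth[ok] - estimates[ok]))
  attr(out, "n_dropped") <- sum(!ok)
  out
}

# Per-replicate seeds derived once from the master seed, so replicates are
# reproducible individually and identical whether run sequentially or not.
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run one Monte Carlo replicate of the PDI estimation study
#'
#' Simulates a cohort, estimates every subject's PDI day by per-subject
#' least squares and by mixed-model BLUP prediction, and records the mean
#' absolute deviation of each estimator from the true crossing days,
#' together with visit-count statistics and bookkeeping counts. When the
#' study configuration carries a survival model, latent event/censoring
#' times are also drawn and "observed" survival datasets are constructed
#' from the true and the LME-estimated PDI days; the replicate then reports
#' reverse-KM median follow-up and the sup distances between the two KM
#' curves and the analytic truth.
#'
#' The replicate is deterministic given `(master_seed, replicate_index)`.
#'
#' @param config A [study_config()] object.
#' @param replicate_index Replicate number (1-based).
#' @return A one-row tibble: `replicate`, `mad_lr`, `mad_lme`, `visit_min`,
#'   `visit_median`, `visit_max`, `n_lr_excluded`, `n_invalid_lr`,
#'   `n_invalid_lme`, `lme_converged`, and — with a survival model —
#'   `revkm_median_true`, `revkm_median_est`, `n_surv_excluded`,
#'   `sup_est_vs_truth`, `sup_est_vs_true_pdi`.
#' @examples
#' cfg <- study_config(n_subjects = 60, n_datasets = 1)
#' run_replicate(cfg, 1)
#' @export
run_replicate <- function(config, replicate_index) {
  stopifnot(inherits(config, "pdi_study_config"), replicate_index >= 1)
  seed <- derive_seeds(config$master_seed, replicate_index)[replicate_index]
  set.seed(seed)

  co <- simulate_cohort(config$population, config$schedule, config$n_subjects)
  thr <- config$population$threshold

  est_lr <- suppressMessages(estimate_pdi_lr(co$data, thr))
  fit <- fit_lme(co$data)
  est_lme <- estimate_pdi_lme(fit, thr)

  truth <- co$truth
  lr_full <- est_lr$pdi_day[match(truth$subject_id, est_lr$subject_id)]
  lme_full <- est_lme$pdi_day[match(truth$subject_id, est_lme$subject_id)]

  mad_lr <- pdi_mad(truth$true_pdi_day, lr_full)
  mad_lme <- pdi_mad(truth$true_pdi_day, lme_full)

  out <- tibble::tibble(
    replicate = as.integer(replicate_index),
    mad_lr = as.numeric(mad_lr),
    mad_lme = as.numeric(mad_lme),
    visit_min = min(truth$n_obs),
    visit_median = stats::median(truth$n_obs),
    visit_max = max(truth$n_obs),
    n_lr_excluded = as.integer(attr(est_lr, "n_excluded") %||% 0L),
    n_invalid_lr = sum(!est_lr$valid),
    n_invalid_lme = sum(!est_lme$valid),
    lme_converged = fit$converged
  )

  if (!is.null(config$survival)) {
    sc <- config$survival
    samples <- simulate_event_censor(sc, config$n_subjects)
    surv_true <- construct_observed_survival(
      samples, truth$true_pdi_day, truth$true_pdi_day, sc$study_end_day)
    surv_est <- construct_observed_survival(
      samples, truth$true_pdi_day, lme_full, sc$study_end_day)
    km_true <- km_estimate(surv_true$duration, surv_true$event)
    km_est <- km_estimate(surv_est$duration, surv_est$event)
    truth_fun <- function(t) true_survival(sc, t)
    out$revkm_median_true <- tryCatch(
      reverse_km_median(surv_true$duration, surv_true$event),
      error = function(e) NA_real_, warning = function(w) NA_real_)
    out$revkm_median_est <- tryCatch(
      reverse_km_median(surv_est$duration, surv_est$event),
      error = function(e) NA_real_, warning = function(w) NA_real_)
    out$n_surv_excluded <- attr(surv_est, "n_excluded")
    out$sup_est_vs_truth <- km_sup_distance(km_est, truth_fun)
    out$sup_est_vs_true_pdi <- km_sup_distance(km_est, km_true)
  }
  out
}

#' Run the full Monte Carlo study
#'
#' Executes [run_replicate()] for every replicate in the configuration and
#' row-binds the results. Replicates whose mixed-model fit did not converge
#' are retained in the output (flagged by `lme_converged`) but dropped by
#' [summarize_study()].
#'
#' @param config A [study_config()] object.
#' @param progress Print a dot per replicate. Default `FALSE`.
#' @return A tibble of replicate rows, of class `pdi_study`.
#' @examples
#' cfg <- study_config(n_subjects = 60, n_datasets = 2)
#' run_study(cfg)
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "pdi_study_config"))
  rows <- purrr::map(seq_len(config$n_datasets), function(r) {
    if (progress) cat(".")
    suppressWarnings(run_replicate(config, r))
  })
  if (progress) cat("\n")
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pdi_study", class(out))
  attr(out, "config") <- config
  out
}

#' Summarise a Monte Carlo study: Table-1-style MAD summary, visit counts
#'
#' Across converged replicates, computes for each estimator the seven-number
#' summary (min, Q1, median, mean, Q3, max, SD) of the per-dataset mean
#' absolute deviations, and the averages of the per-replicate visit-count
#' minimum, median and maximum. Quartiles use linear interpolation between
#' order statistics (`stats::quantile()` type 7); the SD uses the n-1
#' denominator.
#'
#' @param results A `pdi_study` tibble from [run_study()].
#' @return An object of class `pdi_study_summary`: a list with `mad` (tibble,
#'   one row per method), `visits` (one-row tibble of averaged visit
#'   statistics), `n_replicates` and `n_flagged`.
#' @examples
#' cfg <- study_config(n_subjects = 60, n_datasets = 2)
#' summarize_study(run_study(cfg))
#' @export
summarize_study <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("mad_lr", "mad_lme", "lme_converged") %in% names(results)))
  n_flagged <- sum(!results$lme_converged)
  ok <- results[results$lme_converged, ]
  if (nrow(ok) == 0) stop("all replicates flagged as non-converged", call. = FALSE)

  seven <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(min = min(x), q1 = q[1], median = q[2], mean = mean(x),
                   q3 = q[3], max = max(x), sd = stats::sd(x))
  }
  mad <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(method = "LME"), seven(ok$mad_lme)),
    dplyr::bind_cols(tibble::tibble(method = "LR"), seven(ok$mad_lr))
  )
  visits <- tibble::tibble(
    avg_min = mean(ok$visit_min),
    avg_median = mean(ok$visit_median),
    avg_max = mean(ok$visit_max)
  )
  structure(
    list(mad = mad, visits = visits, n_replicates = nrow(ok),
         n_flagged = n_flagged),
    class = "pdi_study_summary"
  )
}

#' @export
print.pdi_study_summary <- function(x, ...) {
  cat(sprintf("PDI estimation study: %d replicate(s)", x$n_replicates))
  if (x$n_flagged > 0) cat(sprintf(" (%d non-converged dropped)", x$n_flagged))
  cat("\nPer-dataset mean absolute deviation (days):\n")
  mad <- as.data.frame(x$mad)
  num <- vapply(mad, is.numeric, logical(1))
  mad[num] <- lapply(mad[num], round, 1)
  print(mad, row.names = FALSE)
  cat(sprintf("Observations per subject (averaged over replicates): min %.1f, median %.2f, max %.1f\n",
              x$visits$avg_min, x$visits$avg_median, x$visits$avg_max))
  invisible(x)
}

#' @export
summary.pdi_study <- function(object, ...) summarize_study(object)

`%||%` <- function(a, b) if (is.null(a)) b else a
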