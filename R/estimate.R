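#' Per-subject least-squares line for one subject's eGFR records
#'
#' Ordinary least squares of eGFR on time for a single subject. At least
#' three records (and two distinct measurement times) are required: with two
#' points the line is saturated and the slope estimate has no residual
#' information to temper it.
#'
#' @param records A data frame with columns `t_days` and `egfr` (one
#'   subject's measurements).
#' @return A one-row tibble: `intercept`, `slope`, `n_obs`.
#' @examples
#' fit_subject_lr(data.frame(t_days = c(0, 500, 1000), egfr = c(25, 19.5, 14)))
#' @export
fit_subject_lr <- function(records) {
  stopifnot(is.data.frame(records), all(c("t_days", "egfr") %in% names(records)))
  if (nrow(records) < 3) {
    stop("at least 3 eGFR measurements are required for a subject-specific ",
         "regression", call. = FALSE)
  }
  if (length(unique(records$t_days)) < 2) {
    stop("all measurement times are identical: slope is not estimable",
         call. = FALSE)
  }
  cf <- stats::lm.fit(cbind(1, records$t_days), records$egfr)$coefficients
  tibble::tibble(intercept = unname(cf[1]), slope = unname(cf[2]),
                 n_obs = nrow(records))
}

#' Per-subject least-squares lines for a whole dataset
#'
#' Applies [fit_subject_lr()] to every subject. Subjects failing its
#' preconditions (fewer than 3 records, or no spread in measurement times)
#' are dropped; the number dropped is reported in the `n_excluded` attribute
#' and via a message.
#'
#' @param data A data frame with columns `subject_id`, `t_days`, `egfr`.
#' @return A tibble `subject_id`, `intercept`, `slope`, `n_obs` with
#'   attribute `n_excluded`.
#' @export
fit_subject_lines <- function(data) {
  stopifnot(all(c("subject_id", "t_days", "egfr") %in% names(data)))
  counts <- dplyr::count(data, .data$subject_id)
  spread <- dplyr::summarise(dplyr::group_by(data, .data$subject_id),
                             n_times = dplyr::n_distinct(.data$t_days))
  eligible <- counts$subject_id[counts$n >= 3 &
                                  spread$n_times[match(counts$subject_id,
                                                       spread$subject_id)] >= 2]
  n_excluded <- nrow(counts) - length(eligible)
  if (n_excluded > 0) {
    message(n_excluded, " subject(s) with fewer than 3 usable records ",
            "excluded from per-subject regression")
  }
  kept <- dplyr::filter(data, .data$subject_id %in% eligible)
  fits <- dplyr::group_modify(
    dplyr::group_by(kept, .data$subject_id),
    function(df, key) fit_subject_lr(df)
  )
  out <- dplyr::ungroup(fits)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Estimate PDI times by per-subject linear regression
#'
#' For each subject with at least three records, fits [fit_subject_lr()] and
#' returns the day the fitted line crosses the threshold,
#' \eqn{\hat t^*_{i,LR} = (\tilde y - \hat\gamma_{0i}) / \hat\gamma_{1i}}.
#' Estimates are unclamped; `valid` is `FALSE` when the fitted slope is zero
#' (no crossing).
#'
#' @param data A data frame with columns `subject_id`, `t_days`, `egfr`.
#' @param threshold eGFR threshold.
#' @return A tibble `subject_id`, `method` (`"LR"`), `pdi_day`, `valid`, with
#'   attribute `n_excluded` (subjects with too few records).
#' @examples
#' d <- data.frame(subject_id = 1, t_days = c(0, 500, 1000),
#'                 egfr = c(25, 19.5, 14))
#' estimate_pdi_lr(d, threshold = 10)
#' @export
estimate_pdi_lr <- function(data, threshold) {
  if (nrow(data) == 0) stop("empty dataset", call. = FALSE)
  lines <- fit_subject_lines(data)
  out <- tibble::tibble(
    subject_id = lines$subject_id,
    method = "LR",
    pdi_day = crossing_or_na(lines$intercept, lines$slope, threshold),
    valid = !is.na(crossing_or_na(lines$intercept, lines$slope, threshold))
  )
  attr(out, "n_excluded") <- attr(lines, "n_excluded")
  out
}

#' Fit the linear mixed effects model to all subjects' eGFR records
#'
#' REML fit of the random-intercept, random-slope model with unstructured
#' 2x2 random-effects covariance, via [lme4::lmer()]. Time is rescaled to
#' years internally for numerical conditioning (day-scale slopes of order
#' 1e-2 with variance of order 1e-6 sit poorly with lme4's convergence
#' checks); all reported coefficients, BLUPs and variance components are
#' mapped back to the day scale.
#'
#' @param data A data frame with columns `subject_id`, `t_days`, `egfr`; at
#'   least two subjects.
#' @return An object of class `pdi_lme`: a list with fixed effects
#'   (`beta0_hat`, `beta1_hat` per day), variance components (`sigma1_hat`,
#'   `sigma2_hat`, `rho_hat`, `sigma_e_hat`), a `blups` tibble
#'   (`subject_id`, `b0_hat`, `b1_hat`), `converged`, `reml_loglik`, and the
#'   underlying `merMod` as `model`.
#' @examples
#' set.seed(1)
#' co <- simulate_cohort(pop_params(), visit_schedule(), 50)
#' fit <- fit_lme(co$data)
#' fit
#' @export
fit_lme <- function(data) {
  stopifnot(all(c("subject_id", "t_days", "egfr") %in% names(data)))
  if (dplyr::n_distinct(data$subject_id) < 2) {
    stop("at least 2 subjects are required for the mixed model", call. = FALSE)
  }
  scale_days <- 365.25
  df <- data.frame(
    id = factor(data$subject_id, levels = unique(data$subject_id)),
    t_yr = data$t_days / scale_days,
    y = data$egfr
  )
  fit <- lme4::lmer(y ~ t_yr + (t_yr | id), data = df, REML = TRUE)
  # Converged means the optimizer itself finished (return code 0). lme4's
  # post-hoc gradient checks routinely fire just above tolerance on large
  # cohorts; those messages are surfaced as warnings but do not flag the
  # fit, and boundary (singular) fits are likewise retained.
  converged <- is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  if (length(msgs) > 0) {
    warning("lme4 reported: ", paste(msgs, collapse = "; "), call. = FALSE)
  }
  fe <- lme4::fixef(fit)
  vc <- lme4::VarCorr(fit)
  sd_id <- attr(vc$id, "stddev")
  rho_hat <- attr(vc$id, "correlation")[1, 2]
  ids <- unique(data$subject_id)
  re <- lme4::ranef(fit)$id
  re <- re[as.character(ids), ] # ranef rows are keyed by factor level
  blups <- tibble::tibble(
    subject_id = ids,
    b0_hat = re[, "(Intercept)"],
    b1_hat = re[, "t_yr"] / scale_days
  )
  structure(
    list(
      beta0_hat = unname(fe["(Intercept)"]),
      beta1_hat = unname(fe["t_yr"]) / scale_days,
      sigma1_hat = unname(sd_id["(Intercept)"]),
      sigma2_hat = unname(sd_id["t_yr"]) / scale_days,
      rho_hat = unname(rho_hat),
      sigma_e_hat = stats::sigma(fit),
      blups = blups,
      converged = converged,
      reml_loglik = as.numeric(stats::logLik(fit)),
      n_subjects = length(ids),
      time_scale_days = scale_days,
      model = fit
    ),
    class = "pdi_lme"
  )
}

#' @export
print.pdi_lme <- function(x, ...) {
  cat("Linear mixed effects fit (REML), random intercept + slope\n")
  cat(sprintf("  fixed effects : beta0 = %.4g, beta1 = %.4g /day\n",
              x$beta0_hat, x$beta1_hat))
  cat(sprintf("  variance comp.: sigma1 = %.4g, sigma2 = %.4g /day, rho = %.3f, sigma_e = %.4g\n",
              x$sigma1_hat, x$sigma2_hat, x$rho_hat, x$sigma_e_hat))
  cat(sprintf("  %d subjects; converged: %s; REML logLik %.2f\n",
              x$n_subjects, x$converged, x$reml_loglik))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fixed effects and variance components of a `pdi_lme` fit
#'
#' @param x A `pdi_lme` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`.
#' @method tidy pdi_lme
#' @export
tidy.pdi_lme <- function(x, ...) {
  tibble::tibble(
    term = c("beta0", "beta1", "sigma1", "sigma2", "rho", "sigma_e"),
    estimate = c(x$beta0_hat, x$beta1_hat, x$sigma1_hat, x$sigma2_hat,
                 x$rho_hat, x$sigma_e_hat)
  )
}

#' One-row summary of a `pdi_lme` fit
#'
#' @param x A `pdi_lme` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_subjects`, `converged`, `reml_loglik`.
#' @method glance pdi_lme
#' @export
glance.pdi_lme <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, converged = x$converged,
                 reml_loglik = x$reml_loglik)
}

#' Estimate PDI times from a fitted mixed model
#'
#' Forms each subject's line as fixed effect plus BLUP,
#' \eqn{\hat\beta_{0i} = \hat\beta_0 + \hat b_{0i}},
#' \eqn{\hat\beta_{1i} = \hat\beta_1 + \hat b_{1i}}, and returns the
#' threshold-crossing day
#' \eqn{\hat t^*_{i,LME} = (\tilde y - \hat\beta_{0i}) / \hat\beta_{1i}}.
#' `valid` is `FALSE` for any subject whose predicted slope is exactly zero.
#'
#' @param fit A `pdi_lme` object from [fit_lme()].
#' @param threshold eGFR threshold.
#' @return A tibble `subject_id`, `method` (`"LME"`), `pdi_day`, `valid`.
#' @export
estimate_pdi_lme <- function(fit, threshold) {
  stopifnot(inherits(fit, "pdi_lme"))
  if (!fit$converged) {
    warning("mixed-model fit did not converge cleanly; PDI estimates may be ",
            "unreliable", call. = FALSE)
  }
  int_i <- fit$beta0_hat + fit$blups$b0_hat
  slo_i <- fit$beta1_hat + fit$blups$b1_hat
  pdi <- crossing_or_na(int_i, slo_i, threshold)
  tibble::tibble(
    subject_id = fit$blups$subject_id,
    method = "LME",
    pdi_day = pdi,
    valid = !is.na(pdi)
  )
}
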