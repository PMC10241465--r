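#' Population parameters of the eGFR decline model
#'
#' The generative truth for simulated cohorts: a random-intercept,
#' random-slope linear mixed effects model
#' \deqn{Y_{ij} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i}) t_{ij} + e_{ij},}
#' with \eqn{(b_{0i}, b_{1i}) \sim N(0, \Sigma)} and
#' \eqn{e_{ij} \sim N(0, \sigma_e^2)}. Time \eqn{t_{ij}} is measured in days
#' since the subject's baseline visit and eGFR in mL/min/1.73m\eqn{^2}.
#' The defaults describe an advanced-CKD population: baseline eGFR averaging
#' 25, declining about 4 units per year, with a dialysis-level threshold of 10.
#'
#' @param beta0 Population intercept (eGFR units). Default 25.
#' @param beta1 Population slope (eGFR units per day). Default -0.011.
#' @param sigma1 SD of the random intercept (eGFR units). Default 6.3.
#' @param sigma2 SD of the random slope (eGFR units per day). Default 0.001.
#' @param rho Correlation between random intercept and slope. Default 0.6.
#' @param sigma_e Residual SD (eGFR units). Default 2.
#' @param threshold eGFR threshold defining putative dialysis initiation
#'   (eGFR units). Default 10, the average eGFR at the start of kidney
#'   replacement therapy among incident US patients.
#'
#' @return An object of class `pdi_pop_params` (a named list).
#' @examples
#' pop_params()
#' pop_params(sigma_e = 1)
#' @export
pop_params <- function(beta0 = 25, beta1 = -0.011, sigma1 = 6.3,
                       sigma2 = 0.001, rho = 0.6, sigma_e = 2,
                       threshold = 10) {
  stopifnot(
    is.numeric(beta0), is.numeric(beta1), length(beta0) == 1L,
    length(beta1) == 1L
  )
  if (sigma1 < 0 || sigma2 < 0 || sigma_e < 0) {
    stop("sigma1, sigma2 and sigma_e must be non-negative", call. = FALSE)
  }
  if (rho <= -1 || rho >= 1) {
    stop("rho must lie strictly between -1 and 1", call. = FALSE)
  }
  if (threshold >= beta0) {
    stop("threshold must lie below the population intercept beta0",
         call. = FALSE)
  }
  structure(
    list(beta0 = beta0, beta1 = beta1, sigma1 = sigma1, sigma2 = sigma2,
         rho = rho, sigma_e = sigma_e, threshold = threshold),
    class = "pdi_pop_params"
  )
}

#' @export
print.pdi_pop_params <- function(x, ...) {
  cat("eGFR decline model (random intercept + slope)\n")
  cat(sprintf("  fixed effects : beta0 = %g, beta1 = %g /day\n",
              x$beta0, x$beta1))
  cat(sprintf("  random effects: sigma1 = %g, sigma2 = %g, rho = %g\n",
              x$sigma1, x$sigma2, x$rho))
  cat(sprintf("  residual SD   : %g\n", x$sigma_e))
  cat(sprintf("  PDI threshold : %g\n", x$threshold))
  invisible(x)
}

#' Covariance matrix of the random effects
#'
#' @param params A [pop_params()] object.
#' @return A 2x2 covariance matrix.
#' @keywords internal
re_covariance <- function(params) {
  off <- params$rho * params$sigma1 * params$sigma2
  matrix(c(params$sigma1^2, off, off, params$sigma2^2), nrow = 2)
}

#' Visit schedule for a staggered-entry longitudinal study
#'
#' Subjects enter the study uniformly over a recruitment window; eGFR is
#' measured at entry and thereafter at intervals of roughly 5, 6 or 7 months,
#' until the next visit would fall past the administrative end of the study.
#'
#' `gap_mode` controls how inter-visit gaps are drawn: `"subject"` (default)
#' assigns each patient one gap length kept for all of their visits (a
#' patient seen on a fixed 5-, 6- or 7-month cadence); `"visit"` redraws the
#' gap before every visit.
#'
#' @param recruitment_window Days over which study entry is uniform.
#'   Default 730 (recruitment over the first two years).
#' @param max_followup Last possible measurement day on the calendar scale.
#'   Default 1825 (five years).
#' @param gap_choices Allowed inter-visit gaps in days, sampled equiprobably.
#'   Default `c(150, 180, 210)`.
#' @param gap_mode `"subject"` or `"visit"`; see Details.
#'
#' @return An object of class `pdi_visit_schedule`.
#' @examples
#' visit_schedule()
#' @export
visit_schedule <- function(recruitment_window = 730, max_followup = 1825,
                           gap_choices = c(150, 180, 210),
                           gap_mode = c("subject", "visit")) {
  gap_mode <- match.arg(gap_mode)
  if (recruitment_window < 0) {
    stop("recruitment_window must be non-negative", call. = FALSE)
  }
  if (max_followup <= recruitment_window) {
    stop("max_followup must exceed recruitment_window", call. = FALSE)
  }
  if (any(gap_choices <= 0)) {
    stop("all gap_choices must be positive", call. = FALSE)
  }
  structure(
    list(recruitment_window = recruitment_window, max_followup = max_followup,
         gap_choices = as.numeric(gap_choices), gap_mode = gap_mode),
    class = "pdi_visit_schedule"
  )
}

#' @export
print.pdi_visit_schedule <- function(x, ...) {
  cat("Visit schedule\n")
  cat(sprintf("  entry uniform on [0, %g] days; visits until day %g\n",
              x$recruitment_window, x$max_followup))
  cat(sprintf("  gaps {%s} days, one draw per %s\n",
              paste(x$gap_choices, collapse = ", "), x$gap_mode))
  invisible(x)
}

#' Latent survival / censoring model for putative survival construction
#'
#' Configures the distributions of the latent event time \eqn{T^*} and
#' censoring time \eqn{C} used when constructing "observed" survival from PDI
#' times. For the exponential family the rates are interpreted per
#' `time_unit_days` days (default 100), so `Exp(0.14)` has mean event time
#' \eqn{100/0.14 \approx 714} days, commensurate with the Weibull
#' alternative of shape 2 and scale 1000 days.
#'
#' @param family `"exponential"` or `"weibull"`.
#' @param event_params For exponential: a single rate. For Weibull: `c(shape,
#'   scale)`. Defaults: 0.14, or `c(2, 1000)`.
#' @param censor_params Likewise for the censoring distribution. Defaults:
#'   0.08, or `c(2, 1250)`.
#' @param time_unit_days Days per distribution time-unit; default 100 for
#'   exponential, 1 for Weibull.
#' @param study_end_day Administrative end of study in days. Default 1825.
#'
#' @return An object of class `pdi_survival_config`.
#' @examples
#' survival_config()
#' survival_config("weibull")
#' @export
survival_config <- function(family = c("exponential", "weibull"),
                            event_params = NULL, censor_params = NULL,
                            time_unit_days = NULL, study_end_day = 1825) {
  family <- match.arg(family)
  if (family == "exponential") {
    if (is.null(event_params)) event_params <- 0.14
    if (is.null(censor_params)) censor_params <- 0.08
    if (is.null(time_unit_days)) time_unit_days <- 100
    stopifnot(length(event_params) == 1L, length(censor_params) == 1L)
  } else {
    if (is.null(event_params)) event_params <- c(2, 1000)
    if (is.null(censor_params)) censor_params <- c(2, 1250)
    if (is.null(time_unit_days)) time_unit_days <- 1
    stopifnot(length(event_params) == 2L, length(censor_params) == 2L)
  }
  if (any(event_params <= 0) || any(censor_params <= 0)) {
    stop("distribution parameters must be positive", call. = FALSE)
  }
  if (time_unit_days <= 0 || study_end_day <= 0) {
    stop("time_unit_days and study_end_day must be positive", call. = FALSE)
  }
  structure(
    list(family = family, event_params = as.numeric(event_params),
         censor_params = as.numeric(censor_params),
         time_unit_days = time_unit_days, study_end_day = study_end_day),
    class = "pdi_survival_config"
  )
}

#' @export
print.pdi_survival_config <- function(x, ...) {
  fmt <- function(p) paste(signif(p, 4), collapse = ", ")
  cat(sprintf("Latent survival model: %s\n", x$family))
  cat(sprintf("  event T* ~ (%s), censoring C ~ (%s)\n",
              fmt(x$event_params), fmt(x$censor_params)))
  cat(sprintf("  time unit %g day(s); study ends day %g\n",
              x$time_unit_days, x$study_end_day))
  invisible(x)
}

#' Configuration of a full Monte Carlo study
#'
#' Bundles the generative model, visit schedule, optional survival model and
#' replication settings for [run_study()].
#'
#' @param population A [pop_params()] object.
#' @param schedule A [visit_schedule()] object.
#' @param survival Optional [survival_config()] object; when supplied,
#'   replicates also carry a putative-survival experiment.
#' @param n_subjects Subjects per simulated dataset. Default 1000.
#' @param n_datasets Number of Monte Carlo replicates. Default 200.
#' @param master_seed Master seed from which per-replicate seeds are derived.
#'
#' @return An object of class `pdi_study_config`.
#' @examples
#' study_config(n_datasets = 5)
#' @export
study_config <- function(population = pop_params(),
                         schedule = visit_schedule(),
                         survival = NULL,
                         n_subjects = 1000, n_datasets = 200,
                         master_seed = 1L) {
  stopifnot(inherits(population, "pdi_pop_params"),
            inherits(schedule, "pdi_visit_schedule"))
  if (!is.null(survival)) stopifnot(inherits(survival, "pdi_survival_config"))
  if (n_subjects < 2) stop("n_subjects must be at least 2", call. = FALSE)
  if (n_datasets < 1) stop("n_datasets must be at least 1", call. = FALSE)
  structure(
    list(population = population, schedule = schedule, survival = survival,
         n_subjects = as.integer(n_subjects),
         n_datasets = as.integer(n_datasets),
         master_seed = as.integer(master_seed)),
    class = "pdi_study_config"
  )
}

#' @export
print.pdi_study_config <- function(x, ...) {
  cat(sprintf("Monte Carlo study: %d datasets x %d subjects (seed %d)\n",
              x$n_datasets, x$n_subjects, x$master_seed))
  print(x$population)
  print(x$schedule)
  if (!is.null(x$survival)) print(x$survival)
  invisible(x)
}
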