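#' Draw subject-level random effects
#'
#' Samples `n` independent pairs \eqn{(b_{0i}, b_{1i})} from the bivariate
#' normal with mean zero and covariance
#' \eqn{\Sigma = [\sigma_1^2, \rho\sigma_1\sigma_2; \rho\sigma_1\sigma_2,
#' \sigma_2^2]}. Uses the session RNG; call `set.seed()` for reproducibility.
#'
#' @param params A [pop_params()] object.
#' @param n Number of subjects.
#' @return A tibble with columns `subject_id`, `b0`, `b1`.
#' @examples
#' set.seed(1)
#' draw_random_effects(pop_params(), 5)
#' @export
draw_random_effects <- function(params, n) {
  stopifnot(inherits(params, "pdi_pop_params"), n >= 1)
  Sigma <- re_covariance(params)
  b <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = Sigma)
  b <- matrix(b, ncol = 2) # mvrnorm drops to a vector when n = 1
  tibble::tibble(subject_id = seq_len(n), b0 = b[, 1], b1 = b[, 2])
}

#' Generate one subject's visit days
#'
#' Entry is uniform on `[0, recruitment_window]`; subsequent visits add
#' inter-visit gaps drawn from `gap_choices` (once per subject or per visit,
#' per the schedule's `gap_mode`) until the next visit would pass
#' `max_followup`. Returned times are calendar days, strictly increasing;
#' there is always at least the entry visit.
#'
#' @param schedule A [visit_schedule()] object.
#' @return Numeric vector of calendar visit days.
#' @examples
#' set.seed(1)
#' generate_visit_times(visit_schedule())
#' @export
generate_visit_times <- function(schedule) {
  stopifnot(inherits(schedule, "pdi_visit_schedule"))
  entry <- stats::runif(1, 0, schedule$recruitment_window)
  choices <- schedule$gap_choices
  per_subject <- schedule$gap_mode == "subject"
  if (per_subject) subject_gap <- choices[sample.int(length(choices), 1L)]
  times <- entry
  repeat {
    gap <- if (per_subject) subject_gap else
      choices[sample.int(length(choices), 1L)]
    nxt <- times[length(times)] + gap
    if (nxt > schedule$max_followup) break
    times <- c(times, nxt)
  }
  times
}

#' Threshold-crossing day of a straight eGFR line
#'
#' The day at which the line `intercept + slope * t` equals `threshold`:
#' \eqn{t^* = (\tilde y - \gamma_0) / \gamma_1}. Values are returned
#' unclamped: a negative crossing (subject already below threshold at
#' baseline) or one beyond the study window is returned as-is.
#'
#' @param intercept,slope Line coefficients (eGFR units; eGFR units per day).
#'   Vectorised.
#' @param threshold eGFR threshold.
#' @return Crossing day(s) in days.
#' @examples
#' pdi_from_line(25, -0.011, 10)
#' @export
pdi_from_line <- function(intercept, slope, threshold) {
  if (any(slope == 0)) {
    stop("slope is zero: the line never crosses the threshold", call. = FALSE)
  }
  (threshold - intercept) / slope
}

# As pdi_from_line but (numerically) zero slopes give NA instead of an
# error; used where a validity flag is reported instead. A slope below
# 1e-12 eGFR/day would take > 1e13 days to move one eGFR unit: no crossing.
crossing_or_na <- function(intercept, slope, threshold) {
  out <- rep(NA_real_, length(slope))
  ok <- is.finite(slope) & abs(slope) > 1e-12 & is.finite(intercept)
  out[ok] <- (threshold - intercept[ok]) / slope[ok]
  out
}

#' Simulate a longitudinal advanced-CKD cohort
#'
#' For each subject, draws random effects and a visit schedule, then
#' generates noisy eGFR values
#' `y = (beta0 + b0) + (beta1 + b1) * t + e`, where `t` is days since the
#' subject's baseline (entry) visit and `e ~ N(0, sigma_e^2)`. Each
#' subject's true PDI day — the day their noiseless line crosses the
#' threshold — is recorded alongside the generating effects.
#'
#' @param params A [pop_params()] object.
#' @param schedule A [visit_schedule()] object.
#' @param n Number of subjects.
#' @return An object of class `pdi_cohort`: a list with
#'   * `data`: tibble `subject_id`, `t_days` (days since baseline), `egfr`;
#'   * `truth`: tibble `subject_id`, `entry_day`, `b0`, `b1`, `beta0_i`,
#'     `beta1_i`, `true_pdi_day`, `n_obs`.
#' @examples
#' set.seed(1)
#' co <- simulate_cohort(pop_params(), visit_schedule(), 20)
#' head(co$data)
#' @export
simulate_cohort <- function(params, schedule, n) {
  stopifnot(inherits(params, "pdi_pop_params"),
            inherits(schedule, "pdi_visit_schedule"), n >= 1)
  re <- draw_random_effects(params, n)
  beta0_i <- params$beta0 + re$b0
  beta1_i <- params$beta1 + re$b1

  visits <- lapply(seq_len(n), function(i) generate_visit_times(schedule))
  n_obs <- vapply(visits, length, integer(1))
  entry <- vapply(visits, function(v) v[1], numeric(1))

  data <- tibble::tibble(
    subject_id = rep(seq_len(n), n_obs),
    t_days = unlist(lapply(visits, function(v) v - v[1]))
  )
  mu <- beta0_i[data$subject_id] + beta1_i[data$subject_id] * data$t_days
  data$egfr <- mu + stats::rnorm(nrow(data), 0, params$sigma_e)

  truth <- tibble::tibble(
    subject_id = re$subject_id,
    entry_day = entry,
    b0 = re$b0, b1 = re$b1,
    beta0_i = beta0_i, beta1_i = beta1_i,
    true_pdi_day = crossing_or_na(beta0_i, beta1_i, params$threshold),
    n_obs = n_obs
  )
  structure(list(data = data, truth = truth, params = params,
                 schedule = schedule),
            class = "pdi_cohort")
}

#' @export
print.pdi_cohort <- function(x, ...) {
  cat(sprintf("Simulated CKD cohort: %d subjects, %d eGFR records\n",
              nrow(x$truth), nrow(x$data)))
  cat(sprintf("  observations per subject: min %d, median %g, max %d\n",
              min(x$truth$n_obs), stats::median(x$truth$n_obs),
              max(x$truth$n_obs)))
  n_below <- sum(x$truth$true_pdi_day <= 0, na.rm = TRUE)
  if (n_below > 0) {
    cat(sprintf("  %d subject(s) start at or below the threshold (true PDI <= 0)\n",
                n_below))
  }
  invisible(x)
}
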