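#' Simulate latent event and censoring times
#'
#' Draws independent latent event times \eqn{T^*} and censoring times
#' \eqn{C} from the configured family, converts them to days via
#' `time_unit_days`, and records \eqn{T_U = \min(T^*, C)} and the event
#' indicator \eqn{\delta = I(T^* \le C)} (the tie, a measure-zero event, is
#' counted as an event).
#'
#' @param config A [survival_config()] object.
#' @param n Number of subjects.
#' @return A tibble `subject_id`, `event_time`, `censor_time`, `t_u`,
#'   `delta` (all times in days).
#' @examples
#' set.seed(1)
#' simulate_event_censor(survival_config(), 5)
#' @export
simulate_event_censor <- function(config, n) {
  stopifnot(inherits(config, "pdi_survival_config"), n >= 1)
  draw <- function(p) {
    if (config$family == "exponential") stats::rexp(n, rate = p[1])
    else stats::rweibull(n, shape = p[1], scale = p[2])
  }
  ev <- draw(config$event_params) * config$time_unit_days
  ce <- draw(config$censor_params) * config$time_unit_days
  tibble::tibble(
    subject_id = seq_len(n),
    event_time = ev,
    censor_time = ce,
    t_u = pmin(ev, ce),
    delta = as.integer(ev <= ce)
  )
}

#' True survival function of the latent event-time distribution
#'
#' \eqn{S(t) = \exp(-\theta t / u)} for the exponential family (rate
#' \eqn{\theta} per `u = time_unit_days` days) and
#' \eqn{S(t) = \exp\{-(t/b)^a\}} for the Weibull family (shape `a`, scale
#' `b` in time units).
#'
#' @param config A [survival_config()] object.
#' @param t Time(s) in days, non-negative.
#' @return Survival probabilities.
#' @examples
#' true_survival(survival_config(), c(0, 495.1))
#' @export
true_survival <- function(config, t) {
  stopifnot(inherits(config, "pdi_survival_config"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  tu <- t / config$time_unit_days
  p <- config$event_params
  if (config$family == "exponential") exp(-p[1] * tu)
  else exp(-(tu / p[2])^p[1])
}

#' Construct "observed" survival durations anchored at estimated PDI times
#'
#' For a conservatively managed patient the latent follow-up clock starts at
#' their (unknown) true PDI day; the analyst can only start follow-up at the
#' estimated PDI day. The calendar outcome day is
#' `min(true_pdi + t_u, study_end_day)` — administrative censoring binds on
#' the calendar scale and forces the event flag to 0 — and the constructed
#' duration is that day minus `est_pdi`. Subjects are excluded (with a
#' reason) when their PDI estimate is missing, their true PDI falls after
#' the study end (no observable follow-up), or the constructed duration is
#' not positive (estimated PDI after the outcome).
#'
#' @param samples A tibble from [simulate_event_censor()] (columns
#'   `subject_id`, `t_u`, `delta`).
#' @param true_pdi Numeric vector of true PDI days, one per sample row.
#' @param est_pdi Numeric vector of estimated PDI days, one per sample row
#'   (`NA` allowed).
#' @param study_end_day Administrative end of study (days).
#' @return A tibble `subject_id`, `duration`, `event`, `excluded`, `reason`,
#'   with attribute `n_excluded`.
#' @examples
#' s <- tibble::tibble(subject_id = 1, t_u = 500, delta = 1L)
#' construct_observed_survival(s, true_pdi = 800, est_pdi = 860,
#'                             study_end_day = 1300)
#' @export
construct_observed_survival <- function(samples, true_pdi, est_pdi,
                                        study_end_day) {
  stopifnot(all(c("subject_id", "t_u", "delta") %in% names(samples)),
            length(true_pdi) == nrow(samples),
            length(est_pdi) == nrow(samples),
            study_end_day > 0)
  outcome_day <- true_pdi + samples$t_u
  capped <- outcome_day >= study_end_day # end-of-study censoring binds at the end day itself
  outcome_day <- pmin(outcome_day, study_end_day)
  event <- ifelse(capped, 0L, samples$delta)
  duration <- outcome_day - est_pdi

  reason <- rep(NA_character_, nrow(samples))
  reason[!is.na(duration) & duration <= 0] <- "nonpositive_duration"
  reason[!is.na(true_pdi) & true_pdi > study_end_day] <- "pdi_after_study_end"
  reason[is.na(true_pdi)] <- "missing_true_pdi"
  reason[is.na(est_pdi)] <- "missing_estimate"
  excluded <- !is.na(reason)

  out <- tibble::tibble(
    subject_id = samples$subject_id,
    duration = ifelse(excluded, NA_real_, duration),
    event = ifelse(excluded, NA_integer_, event),
    excluded = excluded,
    reason = reason
  )
  attr(out, "n_excluded") <- sum(excluded)
  out
}

#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator via [survival::survfit()]; at tied times all
#' events are processed before censorings (the standard convention). The
#' curve starts at 1 at time 0 and is constant between event times.
#'
#' @param durations Positive follow-up durations in days.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return An object of class `pdi_km`: a tibble `time`, `survival`,
#'   `n_risk`, `n_event`, including a `time = 0` row.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 0, 1))
#' @export
km_estimate <- function(durations, events) {
  keep <- !is.na(durations) & !is.na(events)
  durations <- durations[keep]
  events <- events[keep]
  if (length(durations) == 0) stop("no usable observations", call. = FALSE)
  fit <- survival::survfit(survival::Surv(durations, events) ~ 1,
                           conf.type = "none")
  out <- tibble::tibble(
    time = c(0, fit$time),
    survival = c(1, fit$surv),
    n_risk = c(length(durations), fit$n.risk),
    n_event = c(0, fit$n.event)
  )
  class(out) <- c("pdi_km", class(out))
  out
}

#' Median follow-up time by the reverse Kaplan-Meier method
#'
#' The KM estimator applied with the censoring indicator complemented
#' (censorings become "events"), estimating the follow-up distribution; the
#' returned median is the smallest time at which that curve drops to 0.5 or
#' below — the standard "median follow-up".
#'
#' @param durations Follow-up durations in days.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return Median follow-up in days, or `NA` (with a warning) when the
#'   reverse-KM curve never reaches 0.5.
#' @examples
#' reverse_km_median(c(100, 200, 300), c(0, 0, 0))
#' @export
reverse_km_median <- function(durations, events) {
  keep <- !is.na(durations) & !is.na(events)
  durations <- durations[keep]
  events <- events[keep]
  if (length(durations) == 0) stop("no usable observations", call. = FALSE)
  if (all(events == 1)) {
    stop("all observations are events: follow-up distribution is not ",
         "identified", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(durations, 1 - events) ~ 1,
                           conf.type = "none")
  idx <- which(fit$surv <= 0.5)
  if (length(idx) == 0) {
    warning("median follow-up not reached", call. = FALSE)
    return(NA_real_)
  }
  fit$time[idx[1]]
}

#' Supremum distance between two survival curves
#'
#' Maximum absolute difference between two right-continuous step curves (or
#' between a curve and an analytic survival function), evaluated over the
#' union of their step points restricted to the overlap of their time
#' ranges.
#'
#' @param a A `pdi_km` object.
#' @param b A `pdi_km` object, or a function of time returning survival
#'   probabilities (e.g. `function(t) true_survival(cfg, t)`).
#' @return The sup distance (a number in `[0, 1]`).
#' @examples
#' k <- km_estimate(c(1, 2), c(1, 1))
#' km_sup_distance(k, k)
#' @export
km_sup_distance <- function(a, b) {
  stopifnot(inherits(a, "pdi_km"))
  step_eval <- function(curve, t) {
    idx <- findInterval(t, curve$time)
    curve$survival[pmax(idx, 1)]
  }
  if (is.function(b)) {
    grid <- a$time
    max(abs(step_eval(a, grid) - b(grid)))
  } else {
    stopifnot(inherits(b, "pdi_km"))
    lo <- max(min(a$time), min(b$time))
    hi <- min(max(a$time), max(b$time))
    if (lo > hi) stop("curves have disjoint time ranges", call. = FALSE)
    grid <- sort(unique(c(a$time, b$time)))
    grid <- grid[grid >= lo & grid <= hi]
    max(abs(step_eval(a, grid) - step_eval(b, grid)))
  }
}
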