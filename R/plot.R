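#' Spaghetti plot of simulated eGFR trajectories
#'
#' Observed eGFR records of a random subset of subjects, joined per subject,
#' with the population mean line and the PDI threshold overlaid.
#'
#' @param cohort A `pdi_cohort` object.
#' @param n_subjects How many subjects to display. Default 100.
#' @return A ggplot object.
#' @examples
#' set.seed(1)
#' plot_trajectories(simulate_cohort(pop_params(), visit_schedule(), 30), 30)
#' @export
plot_trajectories <- function(cohort, n_subjects = 100) {
  stopifnot(inherits(cohort, "pdi_cohort"))
  ids <- cohort$truth$subject_id
  shown <- if (length(ids) > n_subjects) sample(ids, n_subjects) else ids
  d <- dplyr::filter(cohort$data, .data$subject_id %in% shown)
  p <- cohort$params
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_days, y = .data$egfr,
                                  group = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.3, linewidth = 0.3) +
    ggplot2::geom_abline(intercept = p$beta0, slope = p$beta1,
                         colour = "blue", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = p$threshold, colour = "red",
                        linewidth = 0.8) +
    ggplot2::labs(x = "Days since baseline",
                  y = expression(eGFR ~ (mL/min/1.73 * m^2)),
                  title = "Simulated eGFR trajectories") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Kaplan-Meier curve
#'
#' @param object A `pdi_km` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pdi_km
#' @export
autoplot.pdi_km <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Compare KM curves from true and estimated PDI anchoring with the truth
#'
#' Overlays the KM curve of durations anchored at the true PDI days, the KM
#' curve anchored at estimated PDI days, and (optionally) the analytic
#' survival function of the latent event distribution.
#'
#' @param km_true A `pdi_km` from true-PDI-anchored durations.
#' @param km_est A `pdi_km` from estimated-PDI-anchored durations.
#' @param config Optional [survival_config()] whose analytic survival is
#'   drawn as the reference.
#' @return A ggplot object.
#' @export
plot_survival_comparison <- function(km_true, km_est, config = NULL) {
  stopifnot(inherits(km_true, "pdi_km"), inherits(km_est, "pdi_km"))
  d <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(km_true), curve = "true PDI"),
    dplyr::mutate(tibble::as_tibble(km_est), curve = "estimated PDI")
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival,
                                       colour = .data$curve)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days since start of follow-up",
                  y = "Survival probability", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(config)) {
    grid <- seq(0, max(d$time), length.out = 200)
    ref <- tibble::tibble(time = grid, survival = true_survival(config, grid))
    p <- p + ggplot2::geom_line(data = ref, colour = "blue",
                                linetype = "dashed",
                                ggplot2::aes(group = 1))
  }
  p
}
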