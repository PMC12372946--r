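# ggplot2 methods for simulation, sweep, and MCMC results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' Concentration time courses, faceted by variable with free y scales.
#' VEGF panels are typically viewed on a log scale after injections
#' (`log_y = TRUE`).
#'
#' @param object An `eye_sim` from [simulate_eye()].
#' @param vars Variables to show.
#' @param log_y Log-scale the ordinate?
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eye_sim <- function(object, vars = c("v_aq", "v_vit", "r_aq", "r_vit"),
                             log_y = FALSE, ...) {
  d <- tidyr::pivot_longer(object[, c("time_h", vars)], -"time_h",
                           names_to = "variable", values_to = "conc")
  d$variable <- factor(d$variable, levels = vars)
  g <- ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$conc)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (pmol/mL)")
  if (log_y) g <- g + ggplot2::scale_y_log10()
  g
}

#' Plot a dosing-regimen sweep
#'
#' Max/mean/min vitreal VEGF and total drug versus dosing intensity.
#'
#' @param object A tibble from [regimen_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_regimen_sweep <- function(object, ...) {
  d <- tidyr::pivot_longer(object, c("max", "mean", "min"),
                           names_to = "stat", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$intensity, .data$value,
                                  colour = .data$stat)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~output, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dosing intensity", y = "concentration (pmol/mL)",
                  colour = NULL)
}

#' Plot sensitivity factors
#'
#' Sensitivity factor per parameter and output, with the 1.5 significance
#' threshold marked.
#'
#' @param object Row-bound output of [sweep_parameter()] calls.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$parameter, .data$factor,
                                       fill = .data$output)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1.5, linetype = 2, colour = "red") +
    ggplot2::facet_wrap(~regimen, ncol = 1) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(y = "sensitivity factor (max/min over sweep)", x = NULL)
}

#' Posterior histograms of an MCMC run
#'
#' @param object An `eye_mcmc` from [mcmc_permeability()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eye_mcmc <- function(object, bins = 60, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object$samples),
                           dplyr::everything(),
                           names_to = "term", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "permeability (cm/h)", y = "posterior samples")
}
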