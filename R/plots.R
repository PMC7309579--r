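# ggplot2 helpers for traces, fits, amplitude distributions and effect
# grids.

#' Plot a current trace with optional detected events
#'
#' @param trace a trace tibble.
#' @param events optional event tibble (onsets drawn as marks).
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, events = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$t, y = .data$i)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "current (pA)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0)
    p <- p + ggplot2::geom_vline(
      data = events, ggplot2::aes(xintercept = .data$onset_ms),
      colour = "red", linetype = "dashed", linewidth = 0.3)
  p
}

#' @describeIn plot_trace autoplot method for fitted events: overlays the
#'   best-fit model current on the baseline-subtracted data, with the fit
#'   window implied by the data extent.
#' @param object an `ipsc_fit` object.
#' @param ... unused.
#' @export
autoplot.ipsc_fit <- function(object, ...) {
  d <- object$data
  tt <- d$t - object$onset_ms
  model <- numeric(length(tt))
  model[tt >= 0] <- analytic_current(object$params, tt[tt >= 0])
  d$model <- model
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$i, colour = "data"),
                       linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$model, colour = "fit"),
                       linewidth = 0.6) +
    ggplot2::scale_colour_manual(values = c(data = "grey40",
                                            fit = "firebrick"),
                                 name = NULL) +
    ggplot2::labs(x = "time (ms)", y = "current (pA)",
                  subtitle = sprintf("RMSE %.2f pA (%.1f%% of peak), %s",
                                     object$rmse,
                                     100 * object$rmse_over_peak,
                                     if (object$accepted) "accepted"
                                     else "rejected")) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_trace autoplot method for pseudo-Voigt fits: histogram
#'   of peak amplitudes with the fitted profile.
#' @export
autoplot.pv_fit <- function(object, ...) {
  ggplot2::ggplot(object$histogram, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$density), fill = "grey70",
                      width = diff(object$histogram$mid[1:2])) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick",
                       linewidth = 0.7) +
    ggplot2::labs(x = "peak amplitude (pA)", y = "density",
                  subtitle = sprintf("pseudo-Voigt fit: x0 = %.1f pA, r = %.3f",
                                     object$params$x0, object$params$r)) +
    ggplot2::theme_minimal()
}

#' Effect grid in the style of the condition-comparison figures
#'
#' One tile per (parameter, comparison): blue for a significant increase
#' relative to control, cyan for a significant decrease, gray for a
#' significant change within the control day-to-day range, empty (white)
#' for no significant difference.
#'
#' @param effects output of [classify_effects()]; a `comparison` column is
#'   optional (single comparison assumed otherwise).
#' @return A ggplot object.
#' @export
plot_effect_grid <- function(effects) {
  if (!"comparison" %in% names(effects)) effects$comparison <- "blocked"
  pal <- c("significant-increase" = "#2166ac",
           "significant-decrease" = "#66d9e8",
           "within-control-range" = "grey60",
           "no-difference" = "white")
  ggplot2::ggplot(effects,
                  ggplot2::aes(x = .data$parameter, y = .data$comparison,
                               fill = .data$label)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE, name = NULL) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}
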