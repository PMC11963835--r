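#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_rect geom_function
#'   labs autoplot theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot an eye trace, optionally shading quick phases
#'
#' @param trace A trace tibble.
#' @param seg Optional [segment_phases()] result; its events are shaded.
#' @param channel `"h"`, `"v"` or `"both"`.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, seg = NULL, channel = c("both", "h", "v")) {
  assert_trace(trace)
  channel <- match.arg(channel)
  long <- tidyr::pivot_longer(trace[c("time_s", "h_deg", "v_deg")],
                              c("h_deg", "v_deg"),
                              names_to = "channel", values_to = "deg")
  if (channel != "both") {
    long <- dplyr::filter(long, channel == paste0(!!channel, "_deg"))
  }
  p <- ggplot(long, aes(x = .data$time_s, y = .data$deg))
  if (!is.null(seg) && nrow(seg$events) > 0) {
    p <- p + geom_rect(data = seg$events,
                       aes(xmin = .data$onset_s, xmax = .data$offset_s),
                       ymin = -Inf, ymax = Inf, alpha = 0.25,
                       fill = "orange", inherit.aes = FALSE)
  }
  p + geom_line(linewidth = 0.3) +
    facet_wrap(~channel, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = "eye position (deg)") +
    theme_minimal()
}

#' @describeIn plot_trace autoplot method for segmentations; pass the trace
#'   the segmentation was computed on.
#' @param object A `phase_segmentation`.
#' @param ... Unused.
#' @export
autoplot.phase_segmentation <- function(object, trace, ...) {
  plot_trace(trace, seg = object, channel = "h")
}

#' Plot a time-constant fit
#'
#' Envelope points with the fitted exponential overlaid.
#'
#' @param object A [fit_time_constant()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tc_fit <- function(object, ...) {
  v0 <- object$v0; tau <- object$tau
  ggplot(object$envelope, aes(x = .data$t_s, y = .data$v_dps)) +
    geom_point() +
    geom_function(fun = function(t) v0 * exp(-t / tau), colour = "red") +
    labs(x = "time since step (s)", y = "slow-phase velocity (deg/s)",
         title = sprintf("tau = %.2f s", tau)) +
    theme_minimal()
}

#' Plot a velocity-storage simulation
#'
#' Horizontal eye position and the internal yaw velocity estimate.
#'
#' @param object A [vsm_simulate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vsm_simulation <- function(object, ...) {
  df <- dplyr::left_join(object$trace, object$states, by = "time_s") |>
    dplyr::select(time_s, `eye position (deg)` = h_deg,
                  `yaw estimate (deg/s, CW+)` = omega_est_cw_dps) |>
    tidyr::pivot_longer(-time_s)
  ggplot(df, aes(x = .data$time_s, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~name, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = NULL) +
    theme_minimal()
}
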