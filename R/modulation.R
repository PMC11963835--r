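#' Fit the sinusoidal modulation component (SMC)
#'
#' Least-squares fit of `dc + drift * t + A * sin(2 pi f (t - t0) + phi)` at
#' the known stimulus frequency, on slow-labelled samples only (desaccaded)
#' when a segmentation is supplied. Fixing the frequency to the stimulus
#' makes the fit linear; the drift term keeps residual bias velocity from
#' biasing the amplitude.
#'
#' @param trace A trace tibble.
#' @param seg Optional [segment_phases()] result; when supplied, quick-phase
#'   samples (with a small guard band) are excluded from the fit.
#' @param stimulus_frequency Stimulus frequency in Hz (> 0).
#' @param phase_reference Time (s) to which the fitted phase is referenced.
#' @param channel `"v"` (vertical, the default for otolith testing) or `"h"`.
#' @return An `smc_fit` object with fields `frequency`, `amplitude` (deg,
#'   peak), `phase` (deg in (-180, 180]), `dc_offset`, `drift`, `r_squared`
#'   (`NA` when the residual variance is undefined, e.g. a zero trace) and
#'   `n` (samples used). Supports [generics::tidy()] and
#'   [generics::glance()].
#' @examples
#' t <- seq(0, 30, by = 1 / 60)
#' tr <- tibble::tibble(time_s = t, h_deg = 0, v_deg = 3 * sin(2 * pi * 0.2 * t))
#' fit_smc(tr, stimulus_frequency = 0.2)
#' @export
fit_smc <- function(trace, seg = NULL, stimulus_frequency,
                    phase_reference = 0, channel = c("v", "h")) {
  assert_trace(trace)
  channel <- match.arg(channel)
  if (stimulus_frequency <= 0) {
    stop_invalid("`stimulus_frequency` must be > 0.", "povar_invalid_parameter")
  }
  y_all <- if (channel == "v") trace$v_deg else trace$h_deg
  if (is.null(seg)) {
    m <- rep(TRUE, nrow(trace))
    window <- range(trace$time_s)
  } else {
    stopifnot(inherits(seg, "phase_segmentation"))
    m <- slow_fit_mask(seg, trace$time_s)
    window <- seg$analysis_window
  }
  t <- trace$time_s[m]; y <- y_all[m]
  if (length(t) < 8 || diff(range(t)) < 3 / stimulus_frequency) {
    stop_invalid("Need at least 3 stimulus cycles of slow-phase data.",
                 "povar_insufficient_data")
  }
  tau <- t - phase_reference
  S <- sin(2 * pi * stimulus_frequency * tau)
  C <- cos(2 * pi * stimulus_frequency * tau)
  if (is.null(seg)) {
    X <- cbind(1, tau, S, C)
  } else {
    # desaccade-and-stitch: each inter-quick-phase slow segment gets its own
    # intercept so the sawtooth steps left by quick phases cannot leak into
    # the sinusoid
    idx <- which(m)
    seg_id <- cumsum(c(1, diff(idx) > 1))
    D <- matrix(0, length(idx), max(seg_id))
    D[cbind(seq_along(idx), seg_id)] <- 1
    X <- cbind(D, tau, S, C)
  }
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  p <- length(cf)
  a_s <- unname(cf[p - 1]); a_c <- unname(cf[p])
  dc <- mean(cf[seq_len(p - 3)])
  drift <- unname(cf[p - 2])
  amplitude <- sqrt(a_s^2 + a_c^2)
  phase <- if (amplitude > 1e-12) wrap180(rad2deg(atan2(a_c, a_s))) else 0
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 1e-12) 1 - ssr / sst else NA_real_
  structure(
    list(frequency = stimulus_frequency, amplitude = amplitude, phase = phase,
         dc_offset = dc, drift = drift, r_squared = r2,
         n = length(y), channel = channel, window = window),
    class = "smc_fit")
}

#' @export
print.smc_fit <- function(x, ...) {
  cat("<smc_fit> channel ", x$channel, " at ", x$frequency, " Hz: amplitude ",
      signif(x$amplitude, 4), " deg, phase ", signif(x$phase, 4),
      " deg, r^2 ", signif(x$r_squared, 3), "\n", sep = "")
  invisible(x)
}

#' SMC gain relative to the stimulus
#'
#' For pOVAR/OVAR the fitted peak amplitude is divided by the equivalent tilt
#' angle (deg/deg); for aVOR, by the oscillation amplitude of the yaw
#' stimulus.
#'
#' @param fit An [fit_smc()] result.
#' @param profile The [stimulus_profile()] of the recording.
#' @return Dimensionless gain (numeric scalar).
#' @export
smc_gain <- function(fit, profile) {
  stopifnot(inherits(fit, "smc_fit"), inherits(profile, "stimulus_profile"))
  denom <- if (profile$paradigm %in% c("pOVAR", "OVAR")) {
    equivalent_tilt_angle(profile$main_axis_velocity, profile$radius,
                          profile$gravity)
  } else {
    abs(profile$oscillation_amplitude)
  }
  if (denom <= 0) {
    stop_invalid("Stimulus amplitude is zero; gain undefined.",
                 "povar_undefined_gain")
  }
  fit$amplitude / denom
}

metric_to_fpn <- function(x) {
  if (is.data.frame(x) && "fpn_frequency_hz" %in% names(x)) x$fpn_frequency_hz[1]
  else if (is.numeric(x) && length(x) == 1) x
  else stop_invalid("Expected a nystagmus metrics row or a single frequency.",
                    "povar_invalid_parameter")
}

#' CW/CCW fast-phase asymmetry ratio
#'
#' Ratio of fast-phase nystagmus frequencies between clockwise and
#' counter-clockwise stimulation. The orientation string names the
#' numerator/denominator (control runs are normalized CW/CCW; lesion groups
#' put the lesion-suppressed direction in the numerator so the ratio falls
#' below 1).
#'
#' @param metrics_cw,metrics_ccw [fpn_frequency()] rows (or plain
#'   frequencies) for the CW and CCW runs.
#' @param orientation `"CW/CCW"` or `"CCW/CW"`.
#' @return A one-row tibble: `fpn_cw_hz`, `fpn_ccw_hz`, `orientation`,
#'   `ratio`.
#' @export
asymmetry_ratio <- function(metrics_cw, metrics_ccw,
                            orientation = c("CW/CCW", "CCW/CW")) {
  orientation <- match.arg(orientation)
  f_cw <- metric_to_fpn(metrics_cw)
  f_ccw <- metric_to_fpn(metrics_ccw)
  num <- if (orientation == "CW/CCW") f_cw else f_ccw
  den <- if (orientation == "CW/CCW") f_ccw else f_cw
  if (den <= 0) {
    stop_invalid("Denominator frequency is zero; asymmetry ratio undefined.",
                 "povar_undefined_ratio")
  }
  tibble(fpn_cw_hz = f_cw, fpn_ccw_hz = f_ccw,
         orientation = orientation, ratio = num / den)
}
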