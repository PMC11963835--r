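#' Slow-phase velocity envelope after a velocity step
#'
#' Collapses each inter-quick-phase slow segment to a single point: the
#' median (outlier-robust) slow-phase velocity of the segment at the segment
#' midpoint, with times expressed relative to the step. With no quick phases
#' the whole window decimates into fixed-length bins, so the same exponential
#' fit applies.
#'
#' @param trace A trace tibble.
#' @param seg A [segment_phases()] result for `trace`.
#' @param step_time Time (s) of the velocity step within the trace.
#' @param min_samples Minimum slow samples a segment must contain.
#' @param guard Guard band (s) around quick phases excluded from segments
#'   (the low-pass smears quick-phase velocity into its neighbourhood).
#' @return A tibble: `t_s` (time since step), `v_dps` (median slow-phase
#'   velocity), `n` (samples in the segment).
#' @export
slow_phase_envelope <- function(trace, seg, step_time = 0, min_samples = 8,
                                guard = 0.1) {
  assert_trace(trace)
  stopifnot(inherits(seg, "phase_segmentation"))
  if (step_time < min(trace$time_s) || step_time > max(trace$time_s)) {
    stop_invalid("`step_time` must lie within the trace.", "povar_invalid_parameter")
  }
  d <- smooth_and_differentiate(trace, seg$params$cutoff)
  m <- slow_fit_mask(seg, d$time_s, guard = guard, edge_guard = 0.2)
  m <- m & d$time_s >= step_time
  # break slow samples into contiguous segments (quick phases and guards split them)
  idx <- which(m)
  if (length(idx) == 0) {
    stop_invalid("No slow-phase samples after the step.", "povar_insufficient_data")
  }
  seg_id <- cumsum(c(1, diff(idx) > 1))
  # with no quick phases at all, decimate into ~0.5 s bins instead
  if (nrow(seg$events) == 0) {
    seg_id <- as.integer(cut(d$time_s[idx],
                             breaks = seq(step_time, max(d$time_s) + 0.5, by = 0.5),
                             include.lowest = TRUE))
  }
  env <- tibble(t = d$time_s[idx], v = d$h_vel_dps[idx], g = seg_id) |>
    dplyr::group_by(g) |>
    dplyr::summarise(t_s = median(t) - step_time, v_dps = median(v), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(n >= min_samples) |>
    dplyr::arrange(t_s) |>
    dplyr::select(t_s, v_dps, n)
  if (nrow(env) < 4) {
    stop_invalid("Fewer than 4 slow-phase segments after the step.",
                 "povar_insufficient_data")
  }
  env
}

#' Fit the vestibular time constant
#'
#' Nonlinear least squares of `v0 * exp(-t / tau)` to a slow-phase velocity
#' envelope, initialized by a log-linear regression. The default fit window
#' starts 0.5 s after the step (platform transients) and ends where the
#' envelope falls below 10% of the initial velocity (log-of-noise blowup).
#'
#' @param envelope A [slow_phase_envelope()] tibble (`t_s`, `v_dps`).
#' @param fit_window `c(start, end)` in seconds since the step, or `NULL`
#'   for the default.
#' @return A `tc_fit` object: `tau` (s), `v0` (deg/s), `rmse` (deg/s),
#'   `n_points`, `fit_window`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_time_constant <- function(envelope, fit_window = NULL) {
  stopifnot(is.data.frame(envelope), all(c("t_s", "v_dps") %in% names(envelope)))
  env <- dplyr::arrange(envelope, t_s)
  if (is.null(fit_window)) {
    v0_est <- env$v_dps[which.min(abs(env$t_s))]
    late <- env$t_s >= 0.5
    # truncate at the first point that falls below 10% of the initial
    # velocity: beyond it the envelope is noise, and sign flips there would
    # poison the log-linear step
    s0 <- sign(v0_est)
    below <- late & (abs(env$v_dps) < 0.1 * abs(v0_est) | sign(env$v_dps) != s0)
    t_end <- if (any(below)) min(env$t_s[below]) else max(env$t_s)
    keep <- late & env$t_s < t_end
    # never trim below the minimum point count
    if (sum(keep) < 4) keep <- env$t_s >= 0 & env$t_s <= t_end
    if (sum(keep) < 2) keep <- rep(TRUE, nrow(env))
    fit_window <- range(env$t_s[keep])
  }
  env <- dplyr::filter(env, t_s >= fit_window[1], t_s <= fit_window[2])
  if (nrow(env) < 2) {
    stop_invalid("Need at least 2 envelope points in the fit window.",
                 "povar_insufficient_data")
  }
  s <- sign(median(env$v_dps))
  if (s == 0 || any(sign(env$v_dps) != s)) {
    stop_invalid("Envelope changes sign; cannot fit a single exponential.",
                 "povar_fit_failed")
  }
  # log-linear initializer
  ll <- stats::lm(log(abs(env$v_dps)) ~ env$t_s)
  slope <- unname(coef(ll)[2])
  if (slope >= 0) {
    stop_invalid("Envelope is not decaying; exponential fit failed.",
                 "povar_fit_failed")
  }
  tau0 <- -1 / slope
  v00 <- s * exp(unname(coef(ll)[1]))
  fit <- if (nrow(env) > 2) {
    tryCatch(
      minpack.lm::nlsLM(v_dps ~ v0 * exp(-t_s / tau), data = env,
                        start = list(v0 = v00, tau = tau0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  } else NULL
  if (is.null(fit)) {
    tau <- tau0; v0 <- v00
    rmse <- sqrt(mean((env$v_dps - v0 * exp(-env$t_s / tau))^2))
  } else {
    cf <- coef(fit)
    tau <- unname(cf["tau"]); v0 <- unname(cf["v0"])
    rmse <- sqrt(mean(stats::residuals(fit)^2))
  }
  if (tau <= 0) stop_invalid("Fitted time constant is non-positive.", "povar_fit_failed")
  structure(list(tau = tau, v0 = v0, rmse = rmse, n_points = nrow(env),
                 fit_window = fit_window, envelope = env),
            class = "tc_fit")
}

#' @export
print.tc_fit <- function(x, ...) {
  cat("<tc_fit> tau ", signif(x$tau, 4), " s, v0 ", signif(x$v0, 4),
      " deg/s, rmse ", signif(x$rmse, 3), " (", x$n_points, " points)\n", sep = "")
  invisible(x)
}
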