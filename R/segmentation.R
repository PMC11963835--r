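#' Low-pass filter and differentiate an eye trace
#'
#' Applies a zero-phase (forward-backward) Butterworth low-pass to both
#' channels to remove high-frequency vibration, then computes velocity by
#' first-order and acceleration by second-order central differences, aligned
#' to the input timestamps.
#'
#' @param trace A trace tibble (`time_s`, `h_deg`, `v_deg`).
#' @param cutoff Low-pass cutoff in Hz; must be below the Nyquist frequency.
#' @param order Butterworth order (doubled by the zero-phase pass).
#' @return The trace with added columns `h_filt`, `v_filt`, `h_vel_dps`,
#'   `v_vel_dps`, `h_acc_dps2`.
#' @export
smooth_and_differentiate <- function(trace, cutoff = 12, order = 2) {
  assert_trace(trace)
  fs <- infer_sampling_rate(trace$time_s)
  if (cutoff >= fs / 2) {
    stop_invalid("`cutoff` must be below the Nyquist frequency.",
                 "povar_invalid_parameter")
  }
  bf <- signal::butter(order, cutoff / (fs / 2))
  lp <- function(x) as.numeric(signal::filtfilt(bf, x))
  d1 <- function(x) {
    n <- length(x)
    v <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) * fs
    v
  }
  d2 <- function(x) {
    n <- length(x)
    a <- c(0, x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)], 0) * fs^2
    a
  }
  hf <- lp(trace$h_deg); vf <- lp(trace$v_deg)
  dplyr::mutate(trace,
                h_filt = hf, v_filt = vf,
                h_vel_dps = d1(hf), v_vel_dps = d1(vf),
                h_acc_dps2 = d2(hf))
}

default_window <- function(trace) {
  t_end <- max(trace$time_s)
  if (t_end >= 90) c(60, t_end) else c(min(trace$time_s), t_end)
}

#' Separate fast and slow phases by acceleration thresholding
#'
#' Samples whose absolute (filtered) acceleration exceeds
#' `acceleration_threshold` seed candidate quick-phase events; each event is
#' grown over the contiguous run of samples whose absolute velocity exceeds
#' `velocity_threshold`. Events closer than `refractory` are merged, events
#' shorter than `min_duration` discarded. Everything else is labelled slow
#' (or artifact where the trace carries an artifact quality flag).
#'
#' The default analysis window starts 60 s into the recording (platform
#' start-up is discarded) when the recording is at least 90 s long, and spans
#' the whole recording otherwise.
#'
#' @param trace A trace tibble; a `quality` column, if present, marks
#'   artifact samples.
#' @param velocity_threshold Velocity threshold in deg/s (> 0).
#' @param acceleration_threshold Acceleration threshold in deg/s^2 (> 0).
#' @param cutoff Low-pass cutoff (Hz) for [smooth_and_differentiate()].
#' @param min_duration Minimum event duration (s).
#' @param refractory Events with gaps shorter than this (s) are merged.
#' @param analysis_window `c(start, end)` in seconds, or `NULL` for the
#'   default.
#' @return A `phase_segmentation` object: per-sample `labels`
#'   (slow/fast/artifact), an `events` tibble (`onset_s`, `offset_s`,
#'   `amplitude_deg`, `peak_velocity_dps`, `direction`), the thresholds used
#'   and the analysis window.
#' @export
segment_phases <- function(trace,
                           velocity_threshold = 30,
                           acceleration_threshold = 1000,
                           cutoff = 12,
                           min_duration = 0.015,
                           refractory = 0.05,
                           analysis_window = NULL) {
  assert_trace(trace)
  if (velocity_threshold <= 0 || acceleration_threshold <= 0) {
    stop_invalid("Thresholds must be positive.", "povar_invalid_parameter")
  }
  analysis_window <- analysis_window %||% default_window(trace)
  if (analysis_window[2] <= analysis_window[1] ||
      analysis_window[1] < min(trace$time_s) - 1e-9 ||
      analysis_window[2] > max(trace$time_s) + 1e-9) {
    stop_invalid("`analysis_window` must be a non-empty interval within the trace.",
                 "povar_invalid_window")
  }
  d <- smooth_and_differentiate(trace, cutoff)
  fs <- infer_sampling_rate(trace$time_s)
  n <- nrow(d)
  av <- abs(d$h_vel_dps)
  active <- av > velocity_threshold
  seed <- abs(d$h_acc_dps2) > acceleration_threshold
  # the zero-phase filter has settling transients at the record boundaries;
  # nothing detected there is trustworthy
  edge <- ceiling(0.25 * fs)
  if (n > 2 * edge) {
    active[c(seq_len(edge), (n - edge + 1):n)] <- FALSE
    seed[c(seq_len(edge), (n - edge + 1):n)] <- FALSE
  }

  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & purrr::map_lgl(seq_along(runs$values), function(i) {
    runs$values[i] && any(seed[starts[i]:ends[i]])
  })

  # One supra-threshold run can hold several quick phases (the low-pass
  # smears their velocity pulses together). Local velocity maxima within the
  # run are split apart only where the velocity dips well below both
  # adjacent peaks: a single quick phase has a unimodal velocity pulse (its
  # two acceleration lobes straddle the velocity *maximum*), so a genuine
  # single event never splits.
  dip_frac <- 0.9
  core_frac <- 0.25
  ev <- list()
  for (r in which(keep)) {
    i0 <- starts[r]; i1 <- ends[r]
    seg_av <- av[i0:i1]
    np <- length(seg_av)
    pk <- if (np < 3) which.max(seg_av) + i0 - 1L else {
      locmax <- which(seg_av >= c(-Inf, seg_av[-np]) &
                        seg_av >= c(seg_av[-1], -Inf))
      locmax + i0 - 1L
    }
    # merge peaks not separated by a pronounced dip
    bounds <- i0
    acc_pk <- pk[1]
    if (length(pk) > 1) {
      for (k in 2:length(pk)) {
        mid <- (acc_pk:pk[k])[which.min(av[acc_pk:pk[k]])]
        if (av[mid] < dip_frac * min(av[acc_pk], av[pk[k]])) {
          bounds <- c(bounds, mid)
          acc_pk <- pk[k]
        } else if (av[pk[k]] > av[acc_pk]) acc_pk <- pk[k]
      }
    }
    bounds <- c(bounds, i1 + 1L)
    for (k in seq_len(length(bounds) - 1)) {
      a <- bounds[k]; b <- bounds[k + 1] - 1L
      if (b < a || !any(seed[a:b])) next
      p <- (a:b)[which.max(av[a:b])]
      # event core: contiguous samples above a fraction of this event's own
      # peak velocity — the crossing time is amplitude-invariant, keeping
      # onset timing unbiased for large resets
      thr_ev <- max(velocity_threshold, core_frac * av[p])
      e0 <- p; while (e0 > a && av[e0 - 1L] >= thr_ev) e0 <- e0 - 1L
      e1 <- p; while (e1 < b && av[e1 + 1L] >= thr_ev) e1 <- e1 + 1L
      ev[[length(ev) + 1]] <- c(core0 = e0, core1 = e1, span0 = a, span1 = b)
    }
  }
  ev <- if (length(ev)) as_tibble(do.call(rbind, ev)) else
    tibble(core0 = integer(0), core1 = integer(0),
           span0 = integer(0), span1 = integer(0))
  if (nrow(ev) > 0) {
    ev <- dplyr::filter(ev, (core1 - core0 + 1) / fs >= min_duration)
  }
  if (nrow(ev) > 1) {
    # side-lobe absorption: the zero-phase filter rings around very large
    # quick phases; a neighbouring "event" with a small fraction of the peak
    # velocity within a fifth of a second is ringing, not a quick phase
    pkv <- vapply(seq_len(nrow(ev)),
                  function(i) max(av[ev$core0[i]:ev$core1[i]]), numeric(1))
    repeat {
      gaps <- (ev$core0[-1] - ev$core1[-nrow(ev)]) / fs
      ratio <- pmin(pkv[-1], pkv[-length(pkv)]) /
        pmax(pkv[-1], pkv[-length(pkv)])
      k <- which(gaps < 0.2 & ratio < 0.1)
      if (length(k) == 0) break
      k <- k[1]
      keep_i <- if (pkv[k] >= pkv[k + 1]) k else k + 1
      drop_i <- if (keep_i == k) k + 1 else k
      ev$span0[keep_i] <- min(ev$span0[k], ev$span0[k + 1])
      ev$span1[keep_i] <- max(ev$span1[k], ev$span1[k + 1])
      ev <- ev[-drop_i, ]
      pkv <- pkv[-drop_i]
    }
  }

  labels <- rep("slow", n)
  if (nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) labels[ev$core0[i]:ev$core1[i]] <- "fast"
  }
  if ("quality" %in% names(trace)) labels[trace$quality == "artifact"] <- "artifact"

  events <- if (nrow(ev) == 0) {
    tibble(onset_s = numeric(0), offset_s = numeric(0),
           amplitude_deg = numeric(0), peak_velocity_dps = numeric(0),
           direction = character(0))
  } else {
    purrr::map_dfr(seq_len(nrow(ev)), function(i) {
      # displacement measured over the full supra-threshold span: the
      # low-pass spreads it beyond the timing core
      amp <- d$h_filt[min(ev$span1[i] + 1L, n)] - d$h_filt[max(ev$span0[i] - 1L, 1L)]
      vseg <- d$h_vel_dps[ev$core0[i]:ev$core1[i]]
      tibble(onset_s = d$time_s[ev$core0[i]], offset_s = d$time_s[ev$core1[i]],
             amplitude_deg = amp,
             peak_velocity_dps = vseg[which.max(abs(vseg))],
             direction = if (amp >= 0) "positive" else "negative")
    })
  }

  structure(
    list(labels = tibble(time_s = d$time_s, label = labels),
         events = events,
         params = list(velocity_threshold = velocity_threshold,
                       acceleration_threshold = acceleration_threshold,
                       cutoff = cutoff, min_duration = min_duration,
                       refractory = refractory),
         analysis_window = analysis_window,
         sampling_rate = fs),
    class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat("<phase_segmentation> ", nrow(x$events), " quick-phase events; window [",
      round(x$analysis_window[1], 2), ", ", round(x$analysis_window[2], 2),
      "] s\n", sep = "")
  invisible(x)
}

#' Fast-phase nystagmus frequency
#'
#' Counts quick-phase events whose onset lies inside the analysis window and
#' divides by the window duration. Events straddling the window boundary
#' count if their onset is inside.
#'
#' @param seg A [segment_phases()] result.
#' @return A one-row tibble: `n_quick_phases`, `window_duration_s`,
#'   `fpn_frequency_hz`.
#' @export
fpn_frequency <- function(seg) {
  stopifnot(inherits(seg, "phase_segmentation"))
  w <- seg$analysis_window
  nq <- sum(seg$events$onset_s >= w[1] & seg$events$onset_s < w[2])
  tibble(n_quick_phases = nq,
         window_duration_s = w[2] - w[1],
         fpn_frequency_hz = nq / (w[2] - w[1]))
}

# slow-labelled samples safe for slow-phase model fitting: inside the window,
# away from quick phases (guard), away from filter edge transients
slow_fit_mask <- function(seg, time_s, guard = 0.05, edge_guard = 0.3) {
  lab <- seg$labels$label
  ok <- lab == "slow" &
    time_s >= seg$analysis_window[1] & time_s <= seg$analysis_window[2] &
    time_s >= min(time_s) + edge_guard & time_s <= max(time_s) - edge_guard
  for (i in seq_len(nrow(seg$events))) {
    ok <- ok & !(time_s >= seg$events$onset_s[i] - guard &
                 time_s <= seg$events$offset_s[i] + guard)
  }
  ok
}

#' Mean slow-phase (bias) velocity
#'
#' Averages the velocity series over slow-labelled samples after removing the
#' component at the stimulus frequency by a fit-and-subtract (the intercept
#' of a constant + sinusoid regression on slow-phase velocities). Signed:
#' with CW rotation positive, the bias component is negative.
#'
#' @param trace The trace the segmentation was computed on.
#' @param seg A [segment_phases()] result for `trace`.
#' @param stimulus_frequency Modulation frequency in Hz (0 for none).
#' @return Bias velocity in deg/s (numeric scalar).
#' @export
bias_velocity <- function(trace, seg, stimulus_frequency = 0) {
  assert_trace(trace)
  stopifnot(inherits(seg, "phase_segmentation"))
  d <- smooth_and_differentiate(trace, seg$params$cutoff)
  w <- seg$analysis_window
  in_w <- d$time_s >= w[1] & d$time_s <= w[2]
  frac_slow <- mean(seg$labels$label[in_w] == "slow")
  if (frac_slow < 0.5) {
    stop_invalid("Less than half of the analysis window is slow phase; bias estimate unreliable.",
                 "povar_unreliable_estimate")
  }
  m <- slow_fit_mask(seg, d$time_s)
  v <- d$h_vel_dps[m]; t <- d$time_s[m]
  if (stimulus_frequency > 0) {
    X <- cbind(1, sin(2 * pi * stimulus_frequency * t),
               cos(2 * pi * stimulus_frequency * t))
    unname(stats::lm.fit(X, v)$coefficients[1])
  } else {
    mean(v)
  }
}
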