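#' Scenario parameters for the synthetic eye-movement generator
#'
#' Encodes the phenotypes the generator can emulate. `control` is a healthy
#' mouse; `canal_null` has intact otoliths but no semicircular-canal function
#' (SMC present, no fast-phase nystagmus, no bias); `otolith_null` has intact
#' canals but no otolith function (no steady-state response at all);
#' `uvl_left`/`uvl_right` suppress the quick-phase rate when the stimulus
#' rotates in the lesion-affected direction (CCW for a left lesion, CW for a
#' right lesion); `storage_attenuated` halves both the bias velocity and the
#' quick-phase rate while leaving the SMC untouched (central velocity-storage
#' suppression, as with baclofen).
#'
#' `bias_velocity` is the steady slow-phase velocity offset for CW rotation
#' (negative by convention: CW rotation drives a negative bias); the generator
#' mirrors its sign for CCW rotation.
#'
#' @param scenario One of `"control"`, `"canal_null"`, `"otolith_null"`,
#'   `"uvl_left"`, `"uvl_right"`, `"storage_attenuated"`, `"custom"`.
#' @param smc_amplitude_v,smc_amplitude_h Sinusoidal modulation amplitudes
#'   (deg) of the vertical and horizontal channels.
#' @param bias_velocity Signed steady slow-phase velocity (deg/s) under CW
#'   rotation.
#' @param quick_phase_rate Poisson rate (Hz) of quick phases.
#' @param asymmetry_ratio Multiplier applied to `quick_phase_rate` when the
#'   rotation direction matches the lesion-suppressed direction.
#' @param noise_sd Additive white Gaussian position noise (deg).
#' @param orbital_limit Eye-in-orbit excursion (deg) that forces a resetting
#'   quick phase.
#' @param quick_phase_amplitude_mean,quick_phase_amplitude_sd Normal
#'   parameters (deg) of Poisson-triggered quick-phase amplitudes.
#' @param quick_phase_duration Quick-phase duration (s).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A `scenario_params` object (a named list).
#' @export
scenario_params <- function(scenario = c("control", "canal_null", "otolith_null",
                                         "uvl_left", "uvl_right",
                                         "storage_attenuated", "custom"),
                            smc_amplitude_v = 3,
                            smc_amplitude_h = 1,
                            bias_velocity = -8,
                            quick_phase_rate = 1,
                            asymmetry_ratio = 1,
                            noise_sd = 0.1,
                            orbital_limit = 30,
                            quick_phase_amplitude_mean = 10,
                            quick_phase_amplitude_sd = 2,
                            quick_phase_duration = 0.04,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  p <- list(scenario = scenario,
            smc_amplitude_v = smc_amplitude_v,
            smc_amplitude_h = smc_amplitude_h,
            bias_velocity = bias_velocity,
            quick_phase_rate = quick_phase_rate,
            asymmetry_ratio = asymmetry_ratio,
            noise_sd = noise_sd,
            orbital_limit = orbital_limit,
            quick_phase_amplitude_mean = quick_phase_amplitude_mean,
            quick_phase_amplitude_sd = quick_phase_amplitude_sd,
            quick_phase_duration = quick_phase_duration,
            seed = as.integer(seed),
            suppressed_direction = NA_character_)
  if (p$quick_phase_rate < 0) stop_invalid("`quick_phase_rate` must be >= 0.",
                                           "povar_invalid_parameter")
  if (p$noise_sd < 0) stop_invalid("`noise_sd` must be >= 0.", "povar_invalid_parameter")
  if (p$orbital_limit <= 0) stop_invalid("`orbital_limit` must be > 0.",
                                         "povar_invalid_parameter")
  if (p$asymmetry_ratio <= 0) stop_invalid("`asymmetry_ratio` must be > 0.",
                                           "povar_invalid_parameter")
  switch(scenario,
    canal_null = {
      # otoliths intact, canals dead: modulation survives, nystagmus machinery does not
      p$bias_velocity <- 0
      p$quick_phase_rate <- 0
    },
    otolith_null = {
      # no otolith drive: nothing at steady state
      p$smc_amplitude_v <- 0
      p$smc_amplitude_h <- 0
      p$bias_velocity <- 0
      p$quick_phase_rate <- 0
    },
    uvl_left = {
      if (missing(asymmetry_ratio)) p$asymmetry_ratio <- 0.6
      p$suppressed_direction <- "CCW"
    },
    uvl_right = {
      if (missing(asymmetry_ratio)) p$asymmetry_ratio <- 0.6
      p$suppressed_direction <- "CW"
    },
    storage_attenuated = {
      p$bias_velocity <- p$bias_velocity * 0.5
      p$quick_phase_rate <- p$quick_phase_rate * 0.5
    },
    NULL)
  structure(p, class = "scenario_params")
}

rotation_direction <- function(profile) {
  if (sign(profile$eccentric_axis_velocity) < 0) "CCW" else "CW"
}

# Decide quick-phase event times and amplitudes sample by sample.
# slow_pos(t) must already include drift + SMC; events reset the eye toward
# primary position. Returns list(onset, amplitude, trigger).
simulate_quick_phases <- function(t, slow_pos, dt, rate, bias_sign,
                                  amp_mean, amp_sd, qp_duration, orbital_limit) {
  onsets <- numeric(0)
  amps <- numeric(0)
  trig <- character(0)
  qp_cum <- 0
  min_sep <- qp_duration + 0.02
  last_onset <- -Inf
  p_event <- rate * dt
  n <- length(t)
  u <- if (rate > 0) stats::runif(n) else NULL
  for (i in seq_len(n)) {
    if (t[i] - last_onset < min_sep) next
    pos <- slow_pos[i] + qp_cum
    fire_orbital <- abs(pos) > orbital_limit
    fire_poisson <- rate > 0 && u[i] < p_event
    if (!fire_orbital && !fire_poisson) next
    if (fire_orbital) {
      amp <- -pos
      type <- "orbital"
    } else {
      sign_anti <- if (bias_sign != 0) -bias_sign else -sign(pos)
      if (sign_anti == 0) next
      draw <- max(rnorm(1, amp_mean, amp_sd), 0.5)
      # resetting semantics: capped so the eye is not carried more than ~2 deg
      # past primary position, but never below a 3 deg floor — quick phases
      # smaller than that are below what video-oculography resolves and are
      # not part of the emulated phenomenon
      cap <- 2 - sign_anti * pos
      amp <- sign_anti * max(min(draw, cap), 3)
      type <- "poisson"
    }
    onsets <- c(onsets, t[i])
    amps <- c(amps, amp)
    trig <- c(trig, type)
    qp_cum <- qp_cum + amp
    last_onset <- t[i]
  }
  list(onset = onsets, amplitude = amps, trigger = trig)
}

# Render the cumulative quick-phase displacement: each event is a half-cosine
# step of its amplitude over qp_duration.
render_quick_phases <- function(t, events, qp_duration) {
  disp <- numeric(length(t))
  for (k in seq_along(events$onset)) {
    x <- (t - events$onset[k]) / qp_duration
    disp <- disp + events$amplitude[k] *
      ifelse(x <= 0, 0, ifelse(x >= 1, 1, (1 - cos(pi * x)) / 2))
  }
  disp
}

#' Generate a ground-truthed synthetic eye-movement trace
#'
#' Emulates the structure of mouse eye movements during pOVAR/OVAR: a
#' sinusoidal modulation component (SMC) at the stimulus frequency on both
#' channels, a constant slow-phase drift (bias) on the horizontal channel,
#' resetting quick phases triggered stochastically (Poisson) and
#' deterministically whenever the eye exceeds the orbital limit, and additive
#' Gaussian measurement noise. All randomness is driven by `scenario$seed`.
#'
#' @param profile A [stimulus_profile()] (pOVAR or OVAR).
#' @param scenario A [scenario_params()].
#' @param sampling_rate Samples per second (default 60 Hz).
#' @return A list with `trace` (tibble: `time_s`, `h_deg`, `v_deg`) and
#'   `truth` (list: quick-phase onsets/amplitudes/triggers, true bias, SMC
#'   amplitudes and phase, rotation direction, effective quick-phase rate).
#' @examples
#' prof <- stimulus_profile("pOVAR", 336, 108, duration = 60)
#' syn <- generate_trace(prof, scenario_params(seed = 7), sampling_rate = 60)
#' head(syn$trace)
#' @export
generate_trace <- function(profile, scenario = scenario_params(),
                           sampling_rate = 60) {
  f <- modulation_frequency(profile$eccentric_axis_velocity)
  if (profile$paradigm %in% c("pOVAR", "OVAR") && f > 0 &&
      profile$duration < 10 / f) {
    stop_invalid("Recording must cover at least 10 modulation cycles.",
                 "povar_insufficient_duration")
  }
  dir <- rotation_direction(profile)
  dir_sign <- if (dir == "CW") 1 else -1
  eff_bias <- scenario$bias_velocity * dir_sign
  eff_rate <- scenario$quick_phase_rate *
    if (identical(dir, scenario$suppressed_direction)) scenario$asymmetry_ratio else 1

  dt <- 1 / sampling_rate
  t <- seq(0, profile$duration, by = dt)
  tau_t <- t - profile$phase_reference
  smc_h <- scenario$smc_amplitude_h * dir_sign * sin(2 * pi * f * tau_t)
  smc_v <- scenario$smc_amplitude_v * cos(2 * pi * f * tau_t)
  slow_pos <- eff_bias * t + smc_h

  withr::with_seed(scenario$seed, {
    events <- simulate_quick_phases(
      t, slow_pos, dt, eff_rate, sign(eff_bias),
      scenario$quick_phase_amplitude_mean, scenario$quick_phase_amplitude_sd,
      scenario$quick_phase_duration, scenario$orbital_limit)
    h <- slow_pos + render_quick_phases(t, events, scenario$quick_phase_duration)
    if (scenario$noise_sd > 0) {
      h <- h + rnorm(length(t), 0, scenario$noise_sd)
      smc_v <- smc_v + rnorm(length(t), 0, scenario$noise_sd)
    }
  })

  list(
    trace = tibble(time_s = t, h_deg = h, v_deg = smc_v),
    truth = list(
      quick_phase_onsets = events$onset,
      quick_phase_amplitudes = events$amplitude,
      quick_phase_triggers = events$trigger,
      true_bias_velocity = eff_bias,
      true_smc_amplitude_h = scenario$smc_amplitude_h,
      true_smc_amplitude_v = scenario$smc_amplitude_v,
      true_smc_phase_v = 90,
      rotation_direction = dir,
      effective_quick_phase_rate = eff_rate,
      stimulus_frequency = f,
      sampling_rate = sampling_rate
    )
  )
}

#' Generate a synthetic trapezoidal-angular-velocity (TAV) decay trace
#'
#' Emulates post-step nystagmus: after the velocity step the slow-phase
#' velocity decays as `v0 * exp(-t / tau)`, with resetting quick phases
#' superimposed. Time zero of the returned trace is the step. A `canal_null`
#' scenario abolishes the response (`v0 = 0`); `otolith_null` leaves it intact
#' (the decay is canal-driven).
#'
#' @param profile A [stimulus_profile()] with paradigm `"TAV"`.
#' @param tau True vestibular time constant (s), > 0.
#' @param scenario A [scenario_params()].
#' @param sampling_rate Samples per second.
#' @param v0_gain Slow-phase gain relative to the plateau velocity.
#' @return As [generate_trace()], with `truth$true_time_constant = tau` and
#'   `truth$true_v0` the initial slow-phase velocity.
#' @export
generate_tav_trace <- function(profile, tau, scenario = scenario_params(),
                               sampling_rate = 60, v0_gain = 0.8) {
  if (!identical(profile$paradigm, "TAV")) {
    stop_invalid("`profile` paradigm must be TAV.", "povar_unsupported_paradigm")
  }
  if (tau <= 0) stop_invalid("`tau` must be > 0.", "povar_invalid_parameter")
  canal_factor <- if (scenario$scenario == "canal_null") 0 else 1
  v0 <- v0_gain * abs(profile$tav_plateau_velocity) * canal_factor *
    sign(profile$tav_plateau_velocity)
  dt <- 1 / sampling_rate
  t <- seq(0, profile$duration, by = dt)
  # slow-phase position = integral of the decaying velocity envelope
  slow_pos <- v0 * tau * (1 - exp(-t / tau))

  withr::with_seed(scenario$seed, {
    events <- simulate_quick_phases(
      t, slow_pos, dt, scenario$quick_phase_rate, sign(v0),
      scenario$quick_phase_amplitude_mean, scenario$quick_phase_amplitude_sd,
      scenario$quick_phase_duration, scenario$orbital_limit)
    h <- slow_pos + render_quick_phases(t, events, scenario$quick_phase_duration)
    v <- numeric(length(t))
    if (scenario$noise_sd > 0) {
      h <- h + rnorm(length(t), 0, scenario$noise_sd)
      v <- v + rnorm(length(t), 0, scenario$noise_sd)
    }
  })

  list(
    trace = tibble(time_s = t, h_deg = h, v_deg = v),
    truth = list(
      quick_phase_onsets = events$onset,
      quick_phase_amplitudes = events$amplitude,
      quick_phase_triggers = events$trigger,
      true_time_constant = tau,
      true_v0 = v0,
      sampling_rate = sampling_rate
    )
  )
}

#' Render synthetic eye-video frames with known pupil centers
#'
#' Each frame is a bright background carrying a dark filled ellipse (the
#' pupil) at the commanded center, an optional specular highlight, and
#' optional Gaussian pixel noise. Frames are matrices indexed `[row, col]`
#' with the origin at the top-left pixel; `x` is the column coordinate, `y`
#' the row coordinate.
#'
#' @param pupil_trajectory A data frame or matrix with columns `x`, `y`
#'   (pixel coordinates of the pupil center per frame). Zero rows give an
#'   empty stack.
#' @param frame_shape `c(height, width)` in pixels.
#' @param pupil_axes `c(a, b)` semi-axes in pixels (a along x, b along y).
#' @param noise_sd Gaussian pixel noise SD on the 0-1 intensity scale.
#' @param highlight Add a small specular highlight inside the pupil?
#' @param seed Integer seed for the pixel noise.
#' @return A list with `frames` (list of matrices in `[0, 1]`) and `truth`
#'   (tibble: `frame`, `x`, `y`).
#' @export
generate_frames <- function(pupil_trajectory,
                            frame_shape = c(120, 160),
                            pupil_axes = c(18, 13),
                            noise_sd = 0,
                            highlight = TRUE,
                            seed = 1L) {
  traj <- as.data.frame(pupil_trajectory)
  if (nrow(traj) == 0) {
    return(list(frames = list(),
                truth = tibble(frame = integer(0), x = numeric(0), y = numeric(0))))
  }
  if (!all(c("x", "y") %in% names(traj))) names(traj)[1:2] <- c("x", "y")
  h <- frame_shape[1]; w <- frame_shape[2]
  a <- pupil_axes[1]; b <- pupil_axes[2]
  margin <- max(a, b)
  if (any(traj$x < margin + 1) || any(traj$x > w - margin) ||
      any(traj$y < margin + 1) || any(traj$y > h - margin)) {
    stop_invalid("Pupil trajectory leaves the frame (margin >= major axis required).",
                 "povar_invalid_trajectory")
  }
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)   # column coordinate
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)  # row coordinate
  withr::with_seed(as.integer(seed), {
    frames <- purrr::map(seq_len(nrow(traj)), function(i) {
      cx <- traj$x[i]; cy <- traj$y[i]
      img <- matrix(0.8, nrow = h, ncol = w)
      inside <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
      img[inside] <- 0.15
      if (highlight) {
        hl <- ((xs - (cx - a / 3))^2 + (ys - (cy - b / 3))^2) <= (min(a, b) / 4)^2
        img[hl] <- 0.95
      }
      if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
      pmin(pmax(img, 0), 1)
    })
  })
  list(frames = frames,
       truth = tibble(frame = seq_len(nrow(traj)), x = traj$x, y = traj$y))
}

#' Write / read an eye trace as CSV
#'
#' The on-disk format is a plain CSV with columns `time_s`, `h_deg`, `v_deg`
#' and, when present, `quality`.
#'
#' @param trace A trace tibble.
#' @param path File path.
#' @return `read_trace()` returns the trace tibble; `write_trace()` its input,
#'   invisibly.
#' @export
write_trace <- function(trace, path) {
  assert_trace(trace)
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(trace)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- as_tibble(utils::read.csv(path))
  assert_trace(tr)
  tr
}
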