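#' Velocity-storage model parameters
#'
#' Coefficients of the executable velocity-storage mechanism (VSM): canal
#' high-pass dynamics feed a leaky storage integrator; an internal gravity
#' estimate (tilt estimator) is rotated by the angular-velocity estimate and
#' corrected toward the sensed gravito-inertial acceleration (GIA); the
#' rotation-feedback term `k_F * (GIA x Ghat)` converts the rotating otolith
#' signal into a sustained angular-velocity drive. That feedback is gated by
#' `otolith_gain` and by the canal gain of the side driving the estimated
#' rotation direction — the model's realization of the finding that
#' semicircular-canal input is required for the fast-phase nystagmus during
#' OVAR even though the drive is otolithic.
#'
#' @param canal_time_constant Canal high-pass time constant (s).
#' @param storage_time_constant Storage (leaky integrator) time constant (s);
#'   must exceed the canal time constant.
#' @param k_F Rotation-feedback coefficient, (deg/s) per (m^2/s^4).
#' @param k_G Gravity-estimate correction rate (1/s).
#' @param k_S Canal-to-storage coupling (dimensionless).
#' @param canal_gain_left,canal_gain_right Per-side canal gains in `[0, 1]`.
#'   The left lateral canal drives leftward (CCW) rotation estimates, the
#'   right canal CW estimates.
#' @param otolith_gain Otolith pathway gain in `[0, 1]`.
#' @param vor_gain Slow-phase eye gain on the yaw velocity estimate.
#' @param k_smc_h Horizontal SMC velocity drive, (deg/s) per (m/s^2) of
#'   interaural GIA.
#' @param k_smc_v Vertical SMC position drive, deg per (m/s^2) of
#'   naso-occipital GIA.
#' @param quick_phase_orbital_limit Eye excursion (deg) triggering a reset.
#' @param quick_phase_reset_fraction Fraction of the excursion removed by a
#'   reset, in `(0, 1]`.
#' @return A `vsm_params` object (named list).
#' @export
vsm_params <- function(canal_time_constant = 4,
                       storage_time_constant = 15,
                       k_F = 0.7,
                       k_G = 2,
                       k_S = 0.9,
                       canal_gain_left = 1,
                       canal_gain_right = 1,
                       otolith_gain = 1,
                       vor_gain = 0.8,
                       k_smc_h = 0.25,
                       k_smc_v = 0.5,
                       quick_phase_orbital_limit = 15,
                       quick_phase_reset_fraction = 0.9) {
  p <- as.list(environment())
  if (p$canal_time_constant <= 0 || p$storage_time_constant <= 0) {
    stop_invalid("Time constants must be > 0.", "povar_invalid_parameter")
  }
  if (p$storage_time_constant <= p$canal_time_constant) {
    stop_invalid("`storage_time_constant` must exceed `canal_time_constant`.",
                 "povar_invalid_parameter")
  }
  gains <- c(p$canal_gain_left, p$canal_gain_right, p$otolith_gain)
  if (any(gains < 0 | gains > 1)) {
    stop_invalid("Gains must lie in [0, 1].", "povar_invalid_parameter")
  }
  if (p$quick_phase_reset_fraction <= 0 || p$quick_phase_reset_fraction > 1) {
    stop_invalid("`quick_phase_reset_fraction` must be in (0, 1].",
                 "povar_invalid_parameter")
  }
  structure(p, class = "vsm_params")
}

#' Lesion and manipulation scenarios for the VSM
#'
#' @param name One of `"control"`, `"canal_null"`, `"otolith_null"`,
#'   `"uvl_left"`, `"uvl_right"`, `"storage_attenuated"`.
#' @param base Parameter set to modify.
#' @param uvl_gain Residual canal gain on the lesioned side.
#' @param attenuation Scale applied to the storage time constant and `k_F`
#'   in the `storage_attenuated` scenario.
#' @return A modified [vsm_params()].
#' @export
vsm_scenario <- function(name = c("control", "canal_null", "otolith_null",
                                  "uvl_left", "uvl_right", "storage_attenuated"),
                         base = vsm_params(), uvl_gain = 0.2,
                         attenuation = 0.5) {
  name <- match.arg(name)
  p <- base
  switch(name,
    canal_null = { p$canal_gain_left <- 0; p$canal_gain_right <- 0 },
    otolith_null = { p$otolith_gain <- 0 },
    uvl_left = { p$canal_gain_left <- base$canal_gain_left * uvl_gain },
    uvl_right = { p$canal_gain_right <- base$canal_gain_right * uvl_gain },
    storage_attenuated = {
      p$storage_time_constant <- max(base$storage_time_constant * attenuation,
                                     base$canal_time_constant * 1.01)
      p$k_F <- base$k_F * attenuation
    },
    NULL)
  p
}

#' Initial VSM state
#'
#' The estimator starts at rest with the gravity estimate aligned to gravity.
#'
#' @param gravity Gravitational acceleration (m/s^2).
#' @return A `vsm_state` object: canal high-pass internal state `x_c`
#'   (3-vector, deg/s), gravity estimate `g_est` (3-vector, m/s^2), storage
#'   state `storage` (3-vector, deg/s), `eye_position` (deg). Head-frame
#'   axes: x naso-occipital (+nose), y interaural (+left), z dorso-ventral
#'   (+up); internal angular velocities are right-handed about +z (CCW
#'   positive); the public clockwise-positive yaw is the negated z component.
#' @export
vsm_state <- function(gravity = 9.80665) {
  structure(list(x_c = c(0, 0, 0), g_est = c(0, 0, -gravity),
                 storage = c(0, 0, 0), eye_position = 0),
            class = "vsm_state")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# side-dependent canal gain: CCW (+z internal) signals come from the left
# lateral canal, CW (-z) from the right
side_gain <- function(z, params) {
  if (z > 0) params$canal_gain_left else params$canal_gain_right
}

# time derivative of the continuous part of the state
# y = c(x_c, g_est, storage); omega in internal deg/s, gia in m/s^2
vsm_deriv <- function(y, params, gia, omega) {
  x_c <- y[1:3]; g_est <- y[4:6]; s <- y[7:9]
  canal <- omega - x_c
  c_eff <- canal
  c_eff[3] <- side_gain(canal[3], params) * canal[3]
  feed <- cross3(gia, g_est)
  gate <- params$otolith_gain * side_gain(feed[3], params)
  omega_f <- params$k_F * gate * feed
  omega_est <- c_eff + s
  d_xc <- (omega - x_c) / params$canal_time_constant
  d_g <- -cross3(deg2rad(omega_est), g_est) + params$k_G * (gia - g_est)
  d_s <- (params$k_S * c_eff + omega_f - s) / params$storage_time_constant
  c(d_xc, d_g, d_s)
}

# eye slow-phase velocity (deg/s, public CW-positive eye convention) for a
# given continuous state
vsm_eye_velocity <- function(y, params, gia, omega) {
  x_c <- y[1:3]; s <- y[7:9]
  canal <- omega - x_c
  canal[3] <- side_gain(canal[3], params) * canal[3]
  omega_est_public <- -(canal[3] + s[3])  # internal CCW+ -> public CW+
  smc_drive <- params$otolith_gain * params$k_smc_h * gia[2]
  -params$vor_gain * omega_est_public + smc_drive
}

#' One integration step of the velocity-storage model
#'
#' Advances the continuous state by a fixed-step RK4 update of the canal
#' high-pass, tilt-estimator and leaky-storage dynamics, integrates the eye
#' position, and applies a quick-phase reset when the eye exceeds the
#' orbital limit (the reset removes `quick_phase_reset_fraction` of the
#' excursion and is reported back).
#'
#' @param state A [vsm_state()].
#' @param params A [vsm_params()].
#' @param gia_sample Head-frame GIA 3-vector (m/s^2).
#' @param omega_sample Head angular-velocity 3-vector, internal convention
#'   (deg/s, CCW-positive about +z).
#' @param dt Step (s).
#' @return The updated `vsm_state`, with attributes `eye_velocity` (deg/s)
#'   and `quick_phase` (reset amplitude in deg, or `NA` when no reset
#'   fired).
#' @export
vsm_step <- function(state, params, gia_sample, omega_sample, dt) {
  y <- c(state$x_c, state$g_est, state$storage)
  k1 <- vsm_deriv(y, params, gia_sample, omega_sample)
  k2 <- vsm_deriv(y + dt / 2 * k1, params, gia_sample, omega_sample)
  k3 <- vsm_deriv(y + dt / 2 * k2, params, gia_sample, omega_sample)
  k4 <- vsm_deriv(y + dt * k3, params, gia_sample, omega_sample)
  y1 <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(!is.finite(y1))) {
    bad <- c("canal", "gravity-estimate", "storage")[ceiling(which(!is.finite(y1))[1] / 3)]
    stop_invalid(paste0("VSM integration diverged in the ", bad, " state."),
                 "povar_simulation_unstable")
  }
  ev <- vsm_eye_velocity(y1, params, gia_sample, omega_sample)
  e1 <- state$eye_position + dt * ev
  qp <- NA_real_
  if (abs(e1) > params$quick_phase_orbital_limit) {
    qp <- -e1 * params$quick_phase_reset_fraction
    e1 <- e1 + qp
  }
  out <- structure(list(x_c = y1[1:3], g_est = y1[4:6], storage = y1[7:9],
                        eye_position = e1),
                   class = "vsm_state")
  attr(out, "eye_velocity") <- ev
  attr(out, "quick_phase") <- qp
  out
}

# head angular velocity (internal deg/s 3-vector) as a function of time
vsm_omega_fun <- function(profile) {
  if (profile$paradigm %in% c("pOVAR", "OVAR")) {
    wz <- -(profile$main_axis_velocity + profile$eccentric_axis_velocity)
    function(t) c(0, 0, wz)
  } else if (profile$paradigm == "TAV") {
    v <- profile$tav_plateau_velocity
    r <- abs(profile$tav_ramp)
    t_ramp <- abs(v) / r
    t_stop <- profile$duration / 2
    function(t) {
      w <- if (t < t_ramp) v * t / t_ramp
      else if (t < t_stop) v
      else max(0, 1 - (t - t_stop) / t_ramp) * v
      c(0, 0, -w)
    }
  } else {
    stop_invalid("Simulator supports pOVAR, OVAR and TAV paradigms.",
                 "povar_unsupported_paradigm")
  }
}

vsm_gia_fun <- function(profile) {
  g <- profile$gravity
  if (profile$paradigm %in% c("pOVAR", "OVAR")) {
    omega <- deg2rad(abs(profile$main_axis_velocity))
    cfg <- omega^2 * profile$radius
    f <- modulation_frequency(profile$eccentric_axis_velocity)
    dir <- if (sign(profile$eccentric_axis_velocity) < 0) -1 else 1
    t0 <- profile$phase_reference
    function(t) {
      phi <- dir * 2 * pi * f * (t - t0)
      c(cfg * cos(phi), cfg * sin(phi), -g)
    }
  } else {
    function(t) c(0, 0, -g)
  }
}

#' Simulate the velocity-storage model over a stimulus
#'
#' Integrates [vsm_step()] over the head-frame GIA and angular-velocity time
#' courses of a stimulus profile and returns an eye trace sampled at
#' `sampling_rate` (directly analyzable by [segment_phases()]), the
#' simulator's own quick-phase event log, and steady-state metrics (the
#' steady-state window is the last half of the simulation).
#'
#' @param profile A [stimulus_profile()] (pOVAR, OVAR or TAV).
#' @param params A [vsm_params()].
#' @param duration Simulated duration (s); defaults to the profile duration.
#' @param dt Integration step (s); must satisfy `dt <= 1 / (20 f)` for
#'   modulation frequency `f`.
#' @param sampling_rate Output trace sampling rate (Hz).
#' @return A list: `trace` (tibble `time_s`, `h_deg`, `v_deg`), `events`
#'   (tibble `time_s`, `amplitude_deg`), `states` (tibble of internal states
#'   at the output rate), `metrics` (one-row tibble: `fpn_frequency_hz`,
#'   `n_quick_phases`, `bias_velocity_dps`, `smc_amplitude_v_deg`,
#'   `window_duration_s`), plus the `params` and `profile` used.
#' @export
vsm_simulate <- function(profile, params = vsm_params(), duration = NULL,
                         dt = 0.001, sampling_rate = 60) {
  duration <- duration %||% profile$duration
  f <- if (profile$paradigm %in% c("pOVAR", "OVAR")) {
    modulation_frequency(profile$eccentric_axis_velocity)
  } else 0
  if (f > 0 && dt > 1 / (20 * f)) {
    stop_invalid("`dt` must be at most 1/(20 * modulation frequency).",
                 "povar_invalid_parameter")
  }
  gia_fun <- vsm_gia_fun(profile)
  omega_fun <- vsm_omega_fun(profile)
  n_steps <- ceiling(duration / dt)
  keep_every <- max(1L, round(1 / (sampling_rate * dt)))
  n_out <- floor(n_steps / keep_every) + 1

  state <- vsm_state(profile$gravity)
  out_t <- numeric(n_out); out_h <- numeric(n_out); out_v <- numeric(n_out)
  out_gz <- numeric(n_out); out_west <- numeric(n_out)
  ev_t <- numeric(0); ev_a <- numeric(0)
  g <- profile$gravity

  record <- function(j, t, state, gia) {
    out_t[j] <<- t
    out_h[j] <<- state$eye_position
    out_v[j] <<- params$otolith_gain * params$k_smc_v * gia[1]
    out_gz[j] <<- state$g_est[3]
    out_west[j] <<- -(state$storage[3] +
                        side_gain(state$x_c[3], params) *
                        (omega_fun(t)[3] - state$x_c[3]))
  }
  record(1, 0, state, gia_fun(0))
  j <- 1L
  for (i in seq_len(n_steps)) {
    t <- (i - 1) * dt
    state <- vsm_step(state, params, gia_fun(t), omega_fun(t), dt)
    qp <- attr(state, "quick_phase")
    if (!is.na(qp)) { ev_t <- c(ev_t, t + dt); ev_a <- c(ev_a, qp) }
    if (i %% keep_every == 0) {
      j <- j + 1L
      record(j, i * dt, state, gia_fun(i * dt))
    }
    gn <- sqrt(sum(state$g_est^2))
    if (gn < 0.25 * g || gn > 2 * g) {
      stop_invalid("VSM gravity estimate left its stability bounds.",
                   "povar_simulation_unstable")
    }
  }

  trace <- tibble(time_s = out_t[1:j], h_deg = out_h[1:j], v_deg = out_v[1:j])
  states <- tibble(time_s = out_t[1:j], g_est_z = out_gz[1:j],
                   omega_est_cw_dps = out_west[1:j])
  events <- tibble(time_s = ev_t, amplitude_deg = ev_a)

  w <- c(duration / 2, duration)
  nq <- sum(events$time_s >= w[1] & events$time_s < w[2])
  in_w <- states$time_s >= w[1]
  bias <- -params$vor_gain * mean(states$omega_est_cw_dps[in_w])
  tw <- trace$time_s[in_w]
  smc_v_amp <- if (f > 0) {
    X <- cbind(1, sin(2 * pi * f * tw), cos(2 * pi * f * tw))
    cf <- stats::lm.fit(X, trace$v_deg[in_w])$coefficients
    sqrt(cf[2]^2 + cf[3]^2)
  } else 0
  metrics <- tibble(fpn_frequency_hz = nq / (w[2] - w[1]),
                    n_quick_phases = nq,
                    bias_velocity_dps = bias,
                    smc_amplitude_v_deg = unname(smc_v_amp),
                    window_duration_s = w[2] - w[1])
  structure(list(trace = trace, events = events, states = states,
                 metrics = metrics, params = params, profile = profile),
            class = "vsm_simulation")
}

#' @export
print.vsm_simulation <- function(x, ...) {
  cat("<vsm_simulation> ", x$profile$paradigm, ", ",
      round(max(x$trace$time_s), 1), " s, ", nrow(x$events),
      " quick phases\n", sep = "")
  print(x$metrics)
  invisible(x)
}
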