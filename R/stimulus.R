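#' Describe a turntable stimulus
#'
#' A stimulus profile captures the rotation parameters of a dual-axis
#' (pseudo-OVAR) vestibular test. In pOVAR mode the main axis spins the whole
#' platform so that centrifugal force tilts the gravito-inertial acceleration
#' (GIA) away from Earth vertical, while the eccentric axis sets the frequency
#' at which that tilt sweeps around the animal's head. Positive angular
#' velocities are clockwise (CW) viewed from above.
#'
#' @param paradigm One of `"pOVAR"`, `"OVAR"`, `"aVOR"`, `"TAV"`.
#' @param main_axis_velocity Signed main-axis velocity in deg/s (CW positive).
#' @param eccentric_axis_velocity Signed eccentric-axis velocity in deg/s.
#' @param radius Rotation radius in metres (animal head to main axis).
#' @param duration Recording duration in seconds.
#' @param gravity Gravitational acceleration in m/s^2 (standard gravity).
#' @param phase_reference Time (s) of the absolute phase reference (e.g. an
#'   LED flash); the GIA azimuth is zero at this time.
#' @param tav_plateau_velocity Plateau velocity (deg/s) of the trapezoidal
#'   angular-velocity (TAV) paradigm.
#' @param tav_ramp Ramp (deg/s^2) of the TAV paradigm.
#' @param oscillation_amplitude Peak amplitude (deg) of sinusoidal yaw in the
#'   aVOR paradigm; ignored otherwise.
#'
#' @return A `stimulus_profile` object (a named list).
#' @examples
#' p <- stimulus_profile("pOVAR", main_axis_velocity = 336,
#'                       eccentric_axis_velocity = 72)
#' equivalent_tilt_angle(p$main_axis_velocity, p$radius)
#' modulation_frequency(p$eccentric_axis_velocity)
#' @export
stimulus_profile <- function(paradigm = c("pOVAR", "OVAR", "aVOR", "TAV"),
                             main_axis_velocity = 0,
                             eccentric_axis_velocity = 0,
                             radius = 0.17,
                             duration = 180,
                             gravity = 9.80665,
                             phase_reference = 0,
                             tav_plateau_velocity = 100,
                             tav_ramp = 100,
                             oscillation_amplitude = 10) {
  paradigm <- match.arg(paradigm)
  if (radius <= 0) stop_invalid("`radius` must be > 0.", "povar_invalid_parameter")
  if (duration <= 0) stop_invalid("`duration` must be > 0.", "povar_invalid_parameter")
  if (gravity <= 0) stop_invalid("`gravity` must be > 0.", "povar_invalid_parameter")
  if (paradigm == "pOVAR" &&
      (main_axis_velocity == 0 || eccentric_axis_velocity == 0)) {
    stop_invalid("pOVAR requires nonzero velocities on both axes.",
                 "povar_invalid_parameter")
  }
  structure(
    list(paradigm = paradigm,
         main_axis_velocity = main_axis_velocity,
         eccentric_axis_velocity = eccentric_axis_velocity,
         radius = radius,
         duration = duration,
         gravity = gravity,
         phase_reference = phase_reference,
         tav_plateau_velocity = tav_plateau_velocity,
         tav_ramp = tav_ramp,
         oscillation_amplitude = oscillation_amplitude),
    class = "stimulus_profile"
  )
}

#' @export
print.stimulus_profile <- function(x, ...) {
  cat("<stimulus_profile> ", x$paradigm, "\n", sep = "")
  cat("  main axis: ", x$main_axis_velocity, " deg/s; eccentric axis: ",
      x$eccentric_axis_velocity, " deg/s; radius: ", x$radius, " m\n", sep = "")
  if (x$paradigm %in% c("pOVAR", "OVAR")) {
    cat("  equivalent tilt: ",
        round(equivalent_tilt_angle(x$main_axis_velocity, x$radius, x$gravity), 2),
        " deg (nominal ", nominal_tilt_angle(x$main_axis_velocity, x$radius, x$gravity),
        " deg); modulation: ",
        modulation_frequency(x$eccentric_axis_velocity), " Hz\n", sep = "")
  }
  cat("  duration: ", x$duration, " s\n", sep = "")
  invisible(x)
}

#' Equivalent conventional-OVAR tilt angle
#'
#' During constant rotation at angular velocity omega on an arm of length
#' `radius`, the resultant of gravity and centrifugal acceleration makes an
#' angle `theta = atan(omega^2 * radius / gravity)` with Earth vertical. This
#' is the tilt angle a conventional OVAR test would need to produce the same
#' otolith stimulus.
#'
#' @param main_axis_velocity Main-axis velocity in deg/s (sign ignored);
#'   vectorised.
#' @param radius Rotation radius in metres.
#' @param gravity Gravitational acceleration in m/s^2.
#' @return Tilt angle in degrees, in `[0, 90)`.
#' @seealso [nominal_tilt_angle()] for the rounded label used on stimulus
#'   grids.
#' @export
equivalent_tilt_angle <- function(main_axis_velocity, radius = 0.17,
                                  gravity = 9.80665) {
  if (any(radius <= 0)) stop_invalid("`radius` must be > 0.", "povar_invalid_parameter")
  if (any(gravity <= 0)) stop_invalid("`gravity` must be > 0.", "povar_invalid_parameter")
  omega <- deg2rad(abs(main_axis_velocity))
  rad2deg(atan((omega^2 * radius) / gravity))
}

#' Nominal (rounded) tilt angle
#'
#' Stimulus grids label the equivalent tilt by the nearest multiple of 10
#' degrees (e.g. 186 deg/s at 17 cm is labelled 10 degrees although the exact
#' angle is about 10.35 degrees).
#'
#' @inheritParams equivalent_tilt_angle
#' @param step Rounding step in degrees.
#' @return Tilt label in degrees.
#' @export
nominal_tilt_angle <- function(main_axis_velocity, radius = 0.17,
                               gravity = 9.80665, step = 10) {
  step * round(equivalent_tilt_angle(main_axis_velocity, radius, gravity) / step)
}

#' Otolith modulation frequency
#'
#' The eccentric-axis velocity sets how often the tilted GIA sweeps around the
#' head: one cycle per eccentric-axis revolution, i.e. `|velocity| / 360` Hz.
#'
#' @param eccentric_axis_velocity Eccentric-axis velocity in deg/s
#'   (sign ignored); vectorised.
#' @return Frequency in Hz.
#' @export
modulation_frequency <- function(eccentric_axis_velocity) {
  abs(eccentric_axis_velocity) / 360
}

#' Head-frame gravito-inertial acceleration time course
#'
#' Returns the GIA vector sensed by the otoliths during pOVAR/OVAR, expressed
#' in head-fixed axes: `gia_x` naso-occipital (+nose), `gia_y` interaural
#' (+left), `gia_z` dorso-ventral (+up). Gravity points down (`gia_z` close to
#' `-gravity`); the centrifugal component of magnitude `omega^2 * radius`
#' rotates in the horizontal head plane at the modulation frequency, in the
#' sense set by the sign of the eccentric-axis velocity (CW positive). The
#' azimuth is zero at `phase_reference`.
#'
#' @param profile A [stimulus_profile()] with paradigm pOVAR or OVAR.
#' @param sampling_rate Samples per second.
#' @return A tibble with columns `time_s`, `gia_x`, `gia_y`, `gia_z` (m/s^2)
#'   and `tilt_angle_deg` (constant).
#' @export
gia_timecourse <- function(profile, sampling_rate = 60) {
  if (!inherits(profile, "stimulus_profile")) {
    stop_invalid("`profile` must be a stimulus_profile.", "povar_invalid_parameter")
  }
  if (!profile$paradigm %in% c("pOVAR", "OVAR")) {
    stop_invalid("GIA time course is defined for pOVAR/OVAR paradigms only.",
                 "povar_unsupported_paradigm")
  }
  t <- seq(0, profile$duration, by = 1 / sampling_rate)
  omega <- deg2rad(abs(profile$main_axis_velocity))
  cfg <- omega^2 * profile$radius
  f <- modulation_frequency(profile$eccentric_axis_velocity)
  dir <- sign(profile$eccentric_axis_velocity)
  if (dir == 0) dir <- 1
  phi <- dir * 2 * pi * f * (t - profile$phase_reference)
  tibble(
    time_s = t,
    gia_x = cfg * cos(phi),
    gia_y = cfg * sin(phi),
    gia_z = -profile$gravity,
    tilt_angle_deg = rad2deg(atan(cfg / profile$gravity))
  )
}

#' Read a stimulus profile from YAML or JSON
#'
#' The file must use the `stimulus_profile()` argument names as keys.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` descriptor.
#' @return A [stimulus_profile()].
#' @export
read_profile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_invalid("Profile must be a .yaml/.yml or .json file.", "povar_invalid_parameter")
  }
  do.call(stimulus_profile, lst)
}
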