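#' Analysis configuration
#'
#' Single source of every threshold used by [analyze_recording()]; the
#' effective configuration (and its hash) is embedded in the report as an
#' audit trail.
#'
#' @param velocity_threshold,acceleration_threshold,cutoff,min_duration,refractory,analysis_window
#'   Passed to [segment_phases()].
#' @param scale,origin,max_gap,threshold,sign_flip Passed to [track_frames()]
#'   when the input is a frame stack.
#' @param sampling_rate Frames per second for frame-stack input.
#' @param step_time Velocity-step time (s) for TAV recordings.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(velocity_threshold = 30,
                            acceleration_threshold = 1000,
                            cutoff = 12,
                            min_duration = 0.015,
                            refractory = 0.05,
                            analysis_window = NULL,
                            scale = 0.2,
                            origin = NULL,
                            sampling_rate = 60,
                            max_gap = 3,
                            threshold = NULL,
                            sign_flip = FALSE,
                            step_time = 0) {
  structure(as.list(environment()), class = "analysis_config")
}

#' Analyze one recording end to end
#'
#' Runs the full measurement chain on either a calibrated eye trace or a raw
#' frame stack: (tracking ->) phase segmentation -> fast-phase-nystagmus
#' frequency, bias velocity and SMC fits, plus the time-constant fit for TAV
#' recordings. Deterministic given inputs and configuration.
#'
#' @param x A trace tibble (`time_s`, `h_deg`, `v_deg`) or a list of frames.
#' @param profile The [stimulus_profile()] of the recording.
#' @param config An [analysis_config()].
#' @param id Recording identifier carried into the report.
#' @return A `nystagmus_report`: `metrics` (one-row tibble: quick-phase
#'   count, FPN frequency, bias velocity, SMC amplitudes/gain, time
#'   constant when applicable), the `smc_v`/`smc_h` fits, the `tc` fit (TAV
#'   only), the segmentation, the profile, the config and its hash.
#' @export
analyze_recording <- function(x, profile, config = analysis_config(),
                              id = "recording") {
  stopifnot(inherits(profile, "stimulus_profile"))
  trace <- if (is.data.frame(x)) {
    assert_trace(x)
  } else if (is.list(x)) {
    track_frames(x, scale = config$scale, origin = config$origin,
                 sampling_rate = config$sampling_rate, max_gap = config$max_gap,
                 threshold = config$threshold, sign_flip = config$sign_flip)
  } else {
    stop_invalid("`x` must be a trace tibble or a list of frames.",
                 "povar_invalid_parameter")
  }

  seg <- segment_phases(trace,
                        velocity_threshold = config$velocity_threshold,
                        acceleration_threshold = config$acceleration_threshold,
                        cutoff = config$cutoff,
                        min_duration = config$min_duration,
                        refractory = config$refractory,
                        analysis_window = config$analysis_window)
  met <- fpn_frequency(seg)
  f <- modulation_frequency(profile$eccentric_axis_velocity)

  smc_v <- smc_h <- NULL
  bias <- NA_real_
  gain_v <- NA_real_
  if (profile$paradigm %in% c("pOVAR", "OVAR") && f > 0) {
    smc_v <- fit_smc(trace, seg, f, profile$phase_reference, channel = "v")
    smc_h <- fit_smc(trace, seg, f, profile$phase_reference, channel = "h")
    bias <- tryCatch(bias_velocity(trace, seg, f),
                     povar_unreliable_estimate = function(e) {
                       warning(conditionMessage(e)); NA_real_
                     })
    gain_v <- tryCatch(smc_gain(smc_v, profile),
                       povar_undefined_gain = function(e) NA_real_)
  }

  tc <- NULL
  if (identical(profile$paradigm, "TAV")) {
    env <- slow_phase_envelope(trace, seg, step_time = config$step_time)
    tc <- fit_time_constant(env)
  }

  metrics <- dplyr::mutate(met,
    bias_velocity_dps = bias,
    smc_amplitude_v_deg = if (!is.null(smc_v)) smc_v$amplitude else NA_real_,
    smc_amplitude_h_deg = if (!is.null(smc_h)) smc_h$amplitude else NA_real_,
    smc_gain_v = gain_v,
    time_constant_s = if (!is.null(tc)) tc$tau else NA_real_)

  structure(list(id = id, profile = profile, metrics = metrics,
                 smc_v = smc_v, smc_h = smc_h, tc = tc, segmentation = seg,
                 config = config, config_hash = rlang::hash(config)),
            class = "nystagmus_report")
}

#' @export
print.nystagmus_report <- function(x, ...) {
  cat("<nystagmus_report> ", x$id, " (", x$profile$paradigm, ")\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' Serialize a report to JSON
#'
#' @param report A [analyze_recording()] result.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "nystagmus_report"))
  out <- list(
    id = report$id,
    profile = unclass(report$profile),
    metrics = as.list(report$metrics),
    smc_v = if (!is.null(report$smc_v)) unclass(report$smc_v),
    smc_h = if (!is.null(report$smc_h)) unclass(report$smc_h),
    time_constant = if (!is.null(report$tc)) {
      report$tc$envelope <- NULL
      unclass(report$tc)
    },
    events = as.list(report$segmentation$events),
    config = report$config[!purrr::map_lgl(report$config, is.null)],
    config_hash = report$config_hash)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Compare paired CW and CCW recordings
#'
#' Computes the normalized fast-phase-nystagmus direction ratio with the
#' lesion-dependent orientation convention: control runs report CW/CCW,
#' left-lesion runs CCW/CW and right-lesion runs CW/CCW, so lesion-induced
#' suppression always drives the ratio below 1.
#'
#' @param report_cw,report_ccw Reports from [analyze_recording()] for the CW
#'   and CCW runs of the same paradigm and speeds.
#' @param lesion_orientation `"control"`, `"uvl_left"` or `"uvl_right"`.
#' @return The [asymmetry_ratio()] tibble.
#' @export
paired_direction_analysis <- function(report_cw, report_ccw,
                                      lesion_orientation = c("control",
                                                             "uvl_left",
                                                             "uvl_right")) {
  lesion_orientation <- match.arg(lesion_orientation)
  stopifnot(inherits(report_cw, "nystagmus_report"),
            inherits(report_ccw, "nystagmus_report"))
  p1 <- report_cw$profile; p2 <- report_ccw$profile
  if (!identical(p1$paradigm, p2$paradigm) ||
      abs(p1$main_axis_velocity) != abs(p2$main_axis_velocity) ||
      abs(p1$eccentric_axis_velocity) != abs(p2$eccentric_axis_velocity)) {
    stop_invalid("CW and CCW recordings must share paradigm and axis speeds.",
                 "povar_incompatible_recordings")
  }
  orientation <- if (lesion_orientation == "uvl_left") "CCW/CW" else "CW/CCW"
  asymmetry_ratio(report_cw$metrics, report_ccw$metrics, orientation)
}
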