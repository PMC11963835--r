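#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an SMC fit
#'
#' @param x An [fit_smc()] result.
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @export
tidy.smc_fit <- function(x, ...) {
  tibble(term = c("amplitude", "phase", "dc_offset", "drift"),
         estimate = c(x$amplitude, x$phase, x$dc_offset, x$drift),
         unit = c("deg", "deg", "deg", "deg/s"))
}

#' @rdname tidy.smc_fit
#' @export
glance.smc_fit <- function(x, ...) {
  tibble(frequency_hz = x$frequency, amplitude_deg = x$amplitude,
         phase_deg = x$phase, r_squared = x$r_squared,
         channel = x$channel, n = x$n)
}

#' Tidy a time-constant fit
#'
#' @param x A [fit_time_constant()] result.
#' @param ... Unused.
#' @return A tibble with one row per parameter.
#' @export
tidy.tc_fit <- function(x, ...) {
  tibble(term = c("tau", "v0"), estimate = c(x$tau, x$v0),
         unit = c("s", "deg/s"))
}

#' @rdname tidy.tc_fit
#' @export
glance.tc_fit <- function(x, ...) {
  tibble(tau_s = x$tau, v0_dps = x$v0, rmse_dps = x$rmse,
         n_points = x$n_points)
}

#' Tidy a phase segmentation
#'
#' @param x A [segment_phases()] result.
#' @param ... Unused.
#' @return `tidy()` returns the quick-phase event table; `glance()` a
#'   one-row summary with the FPN frequency.
#' @export
tidy.phase_segmentation <- function(x, ...) x$events

#' @rdname tidy.phase_segmentation
#' @export
glance.phase_segmentation <- function(x, ...) fpn_frequency(x)
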