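#' @importFrom rlang abort %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows summarise group_by ungroup n
#' @importFrom stats lm coef median rnorm rexp sd setNames predict var
#' @keywords internal
"_PACKAGE"

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap an angle in degrees to (-180, 180]
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

stop_invalid <- function(msg, class) {
  abort(msg, class = c(class, "povar_error"))
}

# sampling rate from a uniform time vector, with a uniformity check
infer_sampling_rate <- function(time_s, tol = 1e-6) {
  dt <- diff(time_s)
  if (length(dt) < 1L || any(dt <= 0) || (max(dt) - min(dt)) > tol * mean(dt)) {
    stop_invalid("`time_s` must be strictly increasing with a constant step.",
                 "povar_nonuniform_time")
  }
  1 / mean(dt)
}

assert_trace <- function(trace) {
  need <- c("time_s", "h_deg", "v_deg")
  if (!is.data.frame(trace) || !all(need %in% names(trace))) {
    stop_invalid("`trace` must be a data frame with columns time_s, h_deg, v_deg.",
                 "povar_bad_trace")
  }
  invisible(trace)
}
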