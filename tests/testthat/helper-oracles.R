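# Shared fixtures and independent oracles, built in code at test time.

# Deterministic jerk-nystagmus trace with quick phases at known times:
# the brute-force reference the detector is checked against.
make_jerk_trace <- function(duration = 60, fs = 60, bias = -5,
                            qp_times = seq(2, 58, by = 2), qp_amp = 10,
                            qp_dur = 0.04, smc_a = 0, smc_f = 0.2,
                            noise_sd = 0, seed = 1) {
  t <- seq(0, duration, by = 1 / fs)
  h <- bias * t + smc_a * sin(2 * pi * smc_f * t)
  for (o in qp_times) {
    x <- (t - o) / qp_dur
    h <- h + qp_amp * ifelse(x <= 0, 0, ifelse(x >= 1, 1, (1 - cos(pi * x)) / 2))
  }
  if (noise_sd > 0) {
    h <- h + withr::with_seed(seed, rnorm(length(t), 0, noise_sd))
  }
  tibble::tibble(time_s = t, h_deg = h, v_deg = 0)
}

# Sensitivity / false-discovery statistics by onset matching.
match_stats <- function(truth_onsets, truth_amps, det_onsets, tol = 0.05,
                        min_amp = 5) {
  if (length(truth_onsets) == 0) {
    return(c(sensitivity = NA, fdr = if (length(det_onsets)) 1 else 0))
  }
  matched <- vapply(truth_onsets,
                    function(o) any(abs(det_onsets - o) <= tol), logical(1))
  big <- abs(truth_amps) >= min_amp
  false_det <- vapply(det_onsets,
                      function(o) !any(abs(truth_onsets - o) <= tol), logical(1))
  c(sensitivity = if (any(big)) mean(matched[big]) else NA,
    fdr = if (length(det_onsets)) mean(false_det) else 0)
}

# Reconstruct the cumulative quick-phase displacement from ground truth
# (same half-cosine convention the generator documents).
truth_qp_displacement <- function(t, onsets, amps, qp_dur = 0.04) {
  disp <- numeric(length(t))
  for (k in seq_along(onsets)) {
    x <- (t - onsets[k]) / qp_dur
    disp <- disp + amps[k] * ifelse(x <= 0, 0, ifelse(x >= 1, 1, (1 - cos(pi * x)) / 2))
  }
  disp
}

control_profile <- function(duration = 180, main = 336, ecc = 108) {
  stimulus_profile("pOVAR", main_axis_velocity = main,
                   eccentric_axis_velocity = ecc, duration = duration)
}
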