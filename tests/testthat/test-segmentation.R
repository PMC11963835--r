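test_that("filtered differentiation recovers ramp and sinusoid derivatives", {
  fs <- 60
  t <- seq(0, 20, by = 1 / fs)
  ramp <- tibble::tibble(time_s = t, h_deg = 8 * t, v_deg = 0)
  d <- smooth_and_differentiate(ramp, cutoff = 10)
  interior <- t > 1 & t < 19
  expect_equal(mean(d$h_vel_dps[interior]), 8, tolerance = 1e-3)
  expect_lt(max(abs(d$h_acc_dps2[interior])), 1)

  A <- 5; f <- 1.5
  sine <- tibble::tibble(time_s = t, h_deg = A * sin(2 * pi * f * t), v_deg = 0)
  ds <- smooth_and_differentiate(sine, cutoff = 10)
  expect_equal(max(abs(ds$h_vel_dps[interior])), 2 * pi * f * A, tolerance = 0.02)

  # low-pass reduces noise-velocity variance
  noise <- tibble::tibble(time_s = t,
                          h_deg = withr::with_seed(3, rnorm(length(t), 0, 0.3)),
                          v_deg = 0)
  dn <- smooth_and_differentiate(noise, cutoff = 10)
  raw_vel <- c(0, diff(noise$h_deg)) * fs
  expect_lt(var(dn$h_vel_dps), var(raw_vel))

  expect_error(smooth_and_differentiate(ramp, cutoff = 30),
               class = "povar_invalid_parameter")
})

test_that("the detector finds exactly the injected quick phases with accurate onsets", {
  qp_times <- seq(2, 58, by = 2)  # 29 quick phases
  tr <- make_jerk_trace(duration = 60, bias = -5, qp_times = qp_times,
                        qp_amp = 10, smc_a = 3, smc_f = 0.2,
                        noise_sd = 0.1, seed = 21)
  seg <- segment_phases(tr, analysis_window = c(0, 60))
  expect_equal(nrow(seg$events), length(qp_times))
  err <- sapply(qp_times, function(o) min(abs(seg$events$onset_s - o)))
  expect_lt(max(err), 0.025)
  expect_true(all(seg$events$direction == "positive"))
  expect_equal(seg$events$amplitude_deg, rep(10, length(qp_times)),
               tolerance = 0.15)
})

test_that("slow oscillations and static traces yield no events", {
  t <- seq(0, 60, by = 1 / 60)
  sine <- tibble::tibble(time_s = t, h_deg = 5 * sin(2 * pi * 0.2 * t), v_deg = 0)
  expect_equal(nrow(segment_phases(sine, analysis_window = c(0, 60))$events), 0)
  const <- tibble::tibble(time_s = t, h_deg = 2, v_deg = 0)
  seg <- segment_phases(const, analysis_window = c(0, 60))
  expect_equal(nrow(seg$events), 0)
  expect_true(all(seg$labels$label == "slow"))
})

test_that("noiseless detection matches the brute-force injected-waveform oracle at the boundaries", {
  qp_times <- seq(3, 57, by = 3)
  fs <- 60
  tr <- make_jerk_trace(duration = 60, fs = fs, bias = -3, qp_times = qp_times,
                        qp_amp = 8, noise_sd = 0)
  # brute-force oracle: samples where the injected waveform is active
  seg <- segment_phases(tr, cutoff = 20, analysis_window = c(0, 60))
  expect_equal(nrow(seg$events), length(qp_times))
  for (k in seq_along(qp_times)) {
    expect_lte(abs(seg$events$onset_s[k] - qp_times[k]), 1 / fs + 1e-9)
    expect_lte(abs(seg$events$offset_s[k] - (qp_times[k] + 0.04)), 1 / fs + 1e-9)
  }
})

test_that("segmentation labels are consistent with the event list", {
  syn <- generate_trace(control_profile(duration = 120), scenario_params(seed = 8))
  seg <- segment_phases(syn$trace)
  fast_t <- seg$labels$time_s[seg$labels$label == "fast"]
  inside <- sapply(fast_t, function(x) {
    sum(x >= seg$events$onset_s - 1e-9 & x <= seg$events$offset_s + 1e-9)
  })
  expect_true(all(inside == 1))
  expect_true(all(diff(seg$events$onset_s) > 0))
  expect_true(all(seg$events$offset_s > seg$events$onset_s))
  # fpn_frequency consistency: frequency x duration is an integer count
  m <- fpn_frequency(seg)
  expect_equal(m$fpn_frequency_hz * m$window_duration_s, m$n_quick_phases)
})

test_that("windows and thresholds are validated", {
  tr <- make_jerk_trace(duration = 30)
  expect_error(segment_phases(tr, analysis_window = c(10, 5)),
               class = "povar_invalid_window")
  expect_error(segment_phases(tr, analysis_window = c(0, 50)),
               class = "povar_invalid_window")
  expect_error(segment_phases(tr, velocity_threshold = -5),
               class = "povar_invalid_parameter")
})

test_that("bias velocity is recovered signed and degrades to an error when fast phases dominate", {
  syn <- generate_trace(control_profile(duration = 180), scenario_params(seed = 13))
  seg <- segment_phases(syn$trace)
  b <- bias_velocity(syn$trace, seg, syn$truth$stimulus_frequency)
  expect_equal(b, syn$truth$true_bias_velocity, tolerance = 0.05 * 8)
  expect_lt(b, 0)  # CW stimulation: bias is negative

  # CCW run flips the sign
  synccw <- generate_trace(control_profile(duration = 180, ecc = -108),
                           scenario_params(seed = 13))
  segccw <- segment_phases(synccw$trace)
  expect_gt(bias_velocity(synccw$trace, segccw, 0.3), 0)

  # static trace: zero bias
  t <- seq(0, 100, by = 1 / 60)
  const <- tibble::tibble(time_s = t, h_deg = 0, v_deg = 0)
  segc <- segment_phases(const)
  expect_equal(bias_velocity(const, segc, 0.2), 0, tolerance = 1e-9)
})

test_that("FPN frequency and |bias| co-vary across a quick-phase-rate sweep", {
  rates <- seq(0.3, 1.6, length.out = 10)
  biases <- -seq(3, 12, length.out = 10)
  res <- purrr::map2_dfr(rates, biases, function(r, b) {
    syn <- generate_trace(control_profile(duration = 120),
                          scenario_params(quick_phase_rate = r, bias_velocity = b,
                                          seed = round(1000 * r)))
    seg <- segment_phases(syn$trace)
    tibble::tibble(fpn = fpn_frequency(seg)$fpn_frequency_hz,
                   bias = abs(bias_velocity(syn$trace, seg, 0.3)))
  })
  expect_gt(cor(res$fpn, res$bias, method = "spearman"), 0.9)
})
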