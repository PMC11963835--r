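test_that("a quiet scenario yields an exact sinusoid and identical seeds regenerate bit-identically", {
  prof <- control_profile(duration = 60)
  quiet <- scenario_params("custom", noise_sd = 0, quick_phase_rate = 0,
                           bias_velocity = 0)
  syn <- generate_trace(prof, quiet)
  f <- modulation_frequency(108)
  expect_equal(syn$trace$v_deg, 3 * cos(2 * pi * f * syn$trace$time_s),
               tolerance = 1e-9)
  expect_equal(syn$trace$h_deg, 1 * sin(2 * pi * f * syn$trace$time_s),
               tolerance = 1e-9)
  expect_length(syn$truth$quick_phase_onsets, 0)

  s1 <- generate_trace(prof, scenario_params(seed = 11))
  s2 <- generate_trace(prof, scenario_params(seed = 11))
  expect_identical(s1, s2)
  s3 <- generate_trace(prof, scenario_params(seed = 12))
  expect_false(identical(s1$trace$h_deg, s3$trace$h_deg))
})

test_that("duration must cover ten modulation cycles and onsets respect the refractory spacing", {
  expect_error(generate_trace(control_profile(duration = 20, ecc = 72)),
               class = "povar_insufficient_duration")
  syn <- generate_trace(control_profile(duration = 120), scenario_params(seed = 4))
  on <- syn$truth$quick_phase_onsets
  expect_true(all(diff(on) > scenario_params()$quick_phase_duration))
  expect_true(all(diff(on) > 0))
})

test_that("scenario presets encode the lesion phenotypes", {
  expect_equal(scenario_params("canal_null")$quick_phase_rate, 0)
  expect_equal(scenario_params("canal_null")$smc_amplitude_v, 3)
  ot <- scenario_params("otolith_null")
  expect_equal(c(ot$smc_amplitude_v, ot$smc_amplitude_h, ot$bias_velocity,
                 ot$quick_phase_rate), c(0, 0, 0, 0))
  expect_equal(scenario_params("uvl_left")$suppressed_direction, "CCW")
  expect_equal(scenario_params("uvl_right")$suppressed_direction, "CW")
  st <- scenario_params("storage_attenuated")
  expect_equal(st$bias_velocity, -4)
  expect_equal(st$quick_phase_rate, 0.5)
  expect_error(scenario_params(noise_sd = -1), class = "povar_invalid_parameter")
})

test_that("left-UVL suppresses CCW-rotation quick-phase counts by about the asymmetry ratio", {
  counts <- sapply(1:20, function(s) {
    sc <- scenario_params("uvl_left", asymmetry_ratio = 0.6, seed = s)
    ccw <- generate_trace(control_profile(duration = 180, ecc = -108), sc)
    cw <- generate_trace(control_profile(duration = 180, ecc = 108), sc)
    c(ccw = length(ccw$truth$quick_phase_onsets),
      cw = length(cw$truth$quick_phase_onsets))
  })
  ratio <- sum(counts["ccw", ]) / sum(counts["cw", ])
  expect_gte(ratio, 0.5)
  expect_lte(ratio, 0.7)
})

test_that("Poisson-triggered event counts match the dead-time-corrected rate within 3 SD over 50 seeds", {
  # renewal oracle: a Poisson process thinned by a dead time d has rate
  # lambda / (1 + lambda d)
  sc0 <- scenario_params()
  d <- sc0$quick_phase_duration + 0.02
  lambda <- sc0$quick_phase_rate
  n_pois <- sapply(1:50, function(s) {
    syn <- generate_trace(control_profile(duration = 60), scenario_params(seed = s))
    sum(syn$truth$quick_phase_triggers == "poisson")
  })
  expected <- 60 * lambda / (1 + lambda * d)
  total <- sum(n_pois)
  expect_lt(abs(total - 50 * expected), 3 * sqrt(50 * expected))
})

test_that("removing the injected quick phases recovers bias and SMC to < 1% (noiseless)", {
  prof <- control_profile(duration = 120)
  sc <- scenario_params(noise_sd = 0, seed = 5)
  syn <- generate_trace(prof, sc)
  t <- syn$trace$time_s
  clean <- syn$trace$h_deg -
    truth_qp_displacement(t, syn$truth$quick_phase_onsets,
                          syn$truth$quick_phase_amplitudes)
  f <- syn$truth$stimulus_frequency
  X <- cbind(1, t, sin(2 * pi * f * t), cos(2 * pi * f * t))
  cf <- stats::lm.fit(X, clean)$coefficients
  expect_equal(unname(cf[2]), syn$truth$true_bias_velocity, tolerance = 0.01)
  expect_equal(unname(sqrt(cf[3]^2 + cf[4]^2)), syn$truth$true_smc_amplitude_h,
               tolerance = 0.01)
})

test_that("TAV traces decay with the commanded time constant and respect scenarios", {
  prof <- stimulus_profile("TAV", duration = 40)
  syn <- generate_tav_trace(prof, tau = 5, scenario_params(noise_sd = 0, seed = 2))
  # envelope identity: slow-phase velocity at t = tau is v0 / e
  t <- syn$trace$time_s
  slow <- syn$trace$h_deg -
    truth_qp_displacement(t, syn$truth$quick_phase_onsets,
                          syn$truth$quick_phase_amplitudes)
  i5 <- which.min(abs(t - 5))
  v_at_tau <- (slow[i5 + 1] - slow[i5 - 1]) / (t[i5 + 1] - t[i5 - 1])
  expect_equal(v_at_tau, syn$truth$true_v0 / exp(1), tolerance = 0.01)
  expect_equal(syn$truth$true_time_constant, 5)

  # otolith_null leaves the canal-driven decay intact; canal_null abolishes it
  oto <- generate_tav_trace(prof, tau = 5, scenario_params("otolith_null"))
  expect_equal(oto$truth$true_v0, syn$truth$true_v0)
  cn <- generate_tav_trace(prof, tau = 5, scenario_params("canal_null"))
  expect_equal(cn$truth$true_v0, 0)

  # impaired-storage tau 1 vs control tau 5: envelopes differ > 3x at t = 4 s
  expect_gt(exp(-4 / 5) / exp(-4 / 1), 3)
  expect_error(generate_tav_trace(prof, tau = -1), class = "povar_invalid_parameter")
  expect_error(generate_tav_trace(control_profile(), tau = 5),
               class = "povar_unsupported_paradigm")
})

test_that("trace CSVs round-trip through the readers", {
  syn <- generate_trace(control_profile(duration = 40, ecc = 144),
                        scenario_params(seed = 9))
  f <- tempfile(fileext = ".csv")
  write_trace(syn$trace, f)
  back <- read_trace(f)
  expect_equal(back$h_deg, syn$trace$h_deg, tolerance = 1e-9)
  expect_equal(nrow(back), nrow(syn$trace))
})
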