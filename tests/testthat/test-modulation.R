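test_that("a clean sinusoid is fitted exactly and a zero trace is flagged", {
  t <- seq(0, 30, by = 1 / 60)
  tr <- tibble::tibble(time_s = t, h_deg = 0, v_deg = 3 * sin(2 * pi * 0.2 * t))
  fit <- fit_smc(tr, stimulus_frequency = 0.2, channel = "v")
  expect_equal(fit$amplitude, 3, tolerance = 1e-9)
  expect_equal(fit$phase, 0, tolerance = 1e-6)
  expect_gt(fit$r_squared, 0.999)

  zero <- fit_smc(tr, stimulus_frequency = 0.2, channel = "h")
  expect_equal(zero$amplitude, 0, tolerance = 1e-9)
  expect_true(is.na(zero$r_squared))

  short <- tr[t < 10, ]
  expect_error(fit_smc(short, stimulus_frequency = 0.2),
               class = "povar_insufficient_data")
})

test_that("desaccading recovers the SMC amplitude in the presence of quick phases and noise", {
  syn <- generate_trace(control_profile(duration = 180), scenario_params(seed = 31))
  seg <- segment_phases(syn$trace)
  f <- syn$truth$stimulus_frequency
  fit_v <- fit_smc(syn$trace, seg, f, channel = "v")
  expect_equal(fit_v$amplitude, 3, tolerance = 0.05)
  fit_h <- fit_smc(syn$trace, seg, f, channel = "h")
  expect_equal(fit_h$amplitude, 1, tolerance = 0.05)

  # desaccading must not hurt: with-segmentation error <= without, on
  # scenarios with many quick phases
  for (s in c(1, 2, 3)) {
    synq <- generate_trace(control_profile(duration = 120), scenario_params(seed = s))
    segq <- segment_phases(synq$trace)
    e_with <- abs(fit_smc(synq$trace, segq, 0.3, channel = "h")$amplitude - 1)
    e_without <- abs(fit_smc(synq$trace, NULL, 0.3, channel = "h")$amplitude - 1)
    expect_lte(e_with, e_without + 1e-9)
  }
})

test_that("fitted phase shifts linearly with a time shift, amplitude unchanged", {
  t <- seq(0, 40, by = 1 / 60)
  f <- 0.25
  for (dt in c(0.3, 1.1)) {
    tr0 <- tibble::tibble(time_s = t, h_deg = 0,
                          v_deg = 2 * sin(2 * pi * f * t) + 0.5)
    trs <- tibble::tibble(time_s = t, h_deg = 0,
                          v_deg = 2 * sin(2 * pi * f * (t + dt)) + 0.5)
    f0 <- fit_smc(tr0, stimulus_frequency = f)
    fsh <- fit_smc(trs, stimulus_frequency = f)
    expect_equal(fsh$amplitude, f0$amplitude, tolerance = 1e-6)
    dphi <- (fsh$phase - f0$phase) %% 360
    expect_equal(dphi, (360 * f * dt) %% 360, tolerance = 1e-4)
  }
})

test_that("SMC gain divides amplitude by the stimulus magnitude", {
  t <- seq(0, 60, by = 1 / 60)
  tr <- tibble::tibble(time_s = t, h_deg = 0, v_deg = 3 * sin(2 * pi * 0.2 * t))
  fit <- fit_smc(tr, stimulus_frequency = 0.2)
  # choose the main-axis speed whose exact equivalent tilt is 30 degrees
  v30 <- sqrt(tan(pi / 6) * 9.80665 / 0.17) * 180 / pi
  prof <- stimulus_profile("pOVAR", v30, 72)
  expect_equal(smc_gain(fit, prof), 0.1, tolerance = 1e-6)

  avor <- stimulus_profile("aVOR", oscillation_amplitude = 10)
  expect_equal(smc_gain(fit, avor), 0.3, tolerance = 1e-9)
  avor0 <- stimulus_profile("aVOR", oscillation_amplitude = 0)
  expect_error(smc_gain(fit, avor0), class = "povar_undefined_gain")

  # recovered gain is constant across the tilt sweep at fixed generator gain
  g0 <- 0.1
  for (vm in c(186, 264, 336, 408)) {
    th <- equivalent_tilt_angle(vm)
    syn <- generate_trace(stimulus_profile("pOVAR", vm, 72, duration = 120),
                          scenario_params(smc_amplitude_v = g0 * th, seed = vm))
    seg <- segment_phases(syn$trace)
    fitv <- fit_smc(syn$trace, seg, 0.2, channel = "v")
    expect_equal(smc_gain(fitv, stimulus_profile("pOVAR", vm, 72)), g0,
                 tolerance = 0.05 * g0)
  }
})

test_that("asymmetry ratios follow the orientation convention and invert consistently", {
  expect_equal(asymmetry_ratio(0.8, 0.8)$ratio, 1)
  expect_equal(asymmetry_ratio(0.5, 1.0, "CW/CCW")$ratio, 0.5)
  expect_equal(asymmetry_ratio(0.5, 1.0, "CCW/CW")$ratio, 2)
  r1 <- asymmetry_ratio(0.7, 1.1, "CW/CCW")$ratio
  r2 <- asymmetry_ratio(0.7, 1.1, "CCW/CW")$ratio
  expect_equal(r1 * r2, 1)
  expect_error(asymmetry_ratio(0.5, 0), class = "povar_undefined_ratio")
  m <- tibble::tibble(fpn_frequency_hz = 0.9)
  expect_equal(asymmetry_ratio(m, m)$ratio, 1)
})

test_that("tidiers expose the fit results as tibbles", {
  t <- seq(0, 30, by = 1 / 60)
  tr <- tibble::tibble(time_s = t, h_deg = 0, v_deg = 3 * sin(2 * pi * 0.2 * t))
  fit <- fit_smc(tr, stimulus_frequency = 0.2)
  td <- generics::tidy(fit)
  expect_equal(td$estimate[td$term == "amplitude"], 3, tolerance = 1e-9)
  gl <- generics::glance(fit)
  expect_equal(gl$amplitude_deg, 3, tolerance = 1e-9)
})
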