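test_that("frame synthesis records ground truth verbatim and validates bounds", {
  fr <- generate_frames(data.frame(x = 120, y = 80), frame_shape = c(120, 160))
  expect_length(fr$frames, 1)
  expect_equal(fr$truth$x, 120)
  expect_equal(fr$truth$y, 80)
  empty <- generate_frames(data.frame(x = numeric(0), y = numeric(0)))
  expect_length(empty$frames, 0)
  expect_error(generate_frames(data.frame(x = 5, y = 60)),
               class = "povar_invalid_trajectory")
})

test_that("pupil detection is sub-pixel accurate on synthetic frames and fails loudly otherwise", {
  fr <- generate_frames(data.frame(x = 120, y = 80), noise_sd = 0)
  det <- detect_pupil(fr$frames[[1]])
  expect_true(det$ok)
  expect_lt(sqrt((det$cx - 120)^2 + (det$cy - 80)^2), 0.5)
  # semi-axes recovered in order a >= b > 0
  expect_gt(det$a, det$b)
  expect_gt(det$b, 0)

  expect_equal(detect_pupil(matrix(0.5, 80, 100))$failure_reason, "no_dark_region")

  # two equal dark blobs -> ambiguous, no fabricated center
  img <- matrix(0.8, 100, 140)
  img[20:40, 20:40] <- 0.1
  img[60:80, 90:110] <- 0.1
  amb <- detect_pupil(img)
  expect_false(amb$ok)
  expect_equal(amb$failure_reason, "multiple_ambiguous")

  # a circular pupil: ellipse-fit center matches the dark-pixel centroid
  frc <- generate_frames(data.frame(x = 70, y = 60), pupil_axes = c(14, 14),
                         highlight = FALSE)
  img <- frc$frames[[1]]
  detc <- detect_pupil(img)
  dark <- which(img < 0.5, arr.ind = TRUE)
  expect_lt(abs(detc$cx - mean(dark[, "col"])), 0.1)
  expect_lt(abs(detc$cy - mean(dark[, "row"])), 0.1)
})

test_that("detection is translation-equivariant within 0.1 px", {
  base <- generate_frames(data.frame(x = 60, y = 50))$frames[[1]]
  shifted <- generate_frames(data.frame(x = 67, y = 47))$frames[[1]]
  d0 <- detect_pupil(base); d1 <- detect_pupil(shifted)
  expect_lt(abs((d1$cx - d0$cx) - 7), 0.1)
  expect_lt(abs((d1$cy - d0$cy) - (-3)), 0.1)
})

test_that("detection error is statistically non-decreasing in pixel noise", {
  noise_levels <- c(0, 0.03, 0.08, 0.15)
  mean_err <- sapply(noise_levels, function(ns) {
    errs <- sapply(1:10, function(s) {
      fr <- generate_frames(data.frame(x = 75 + 3 * s %% 5, y = 55),
                            noise_sd = ns, seed = s)
      d <- detect_pupil(fr$frames[[1]])
      if (!d$ok) return(NA)
      sqrt((d$cx - fr$truth$x)^2 + (d$cy - fr$truth$y)^2)
    })
    mean(errs, na.rm = TRUE)
  })
  expect_true(all(diff(mean_err) > -0.05))
  expect_gt(mean_err[4], mean_err[1])
})

test_that("video tracking calibrates to degrees and recovers the commanded amplitude", {
  n <- 100
  amp_px <- 25
  traj <- data.frame(x = 80 + amp_px * sin(2 * pi * 0.05 * (0:(n - 1))),
                     y = 60 + 8 * cos(2 * pi * 0.05 * (0:(n - 1))))
  fr <- generate_frames(traj, noise_sd = 0)
  tr <- track_frames(fr$frames, scale = 0.2, origin = c(80, 60), sampling_rate = 60)
  expect_equal(nrow(tr), n)
  f_hz <- 0.05 * 60
  fit <- fit_smc(tr, stimulus_frequency = f_hz, channel = "h")
  expect_equal(fit$amplitude, amp_px * 0.2, tolerance = 0.02)
  # y grows downward in the image, so up is positive in degrees
  expect_equal(tr$v_deg[1], -8 * 0.2, tolerance = 0.05)

  # constant trajectory -> constant trace
  frc <- generate_frames(data.frame(x = rep(80, 10), y = rep(60, 10)))
  trc <- track_frames(frc$frames, scale = 0.2, origin = c(80, 60))
  expect_lt(diff(range(trc$h_deg)), 0.1)
})

test_that("failed frames are interpolated within max_gap and flagged as artifacts beyond it", {
  fr <- generate_frames(data.frame(x = seq(60, 100, length.out = 20),
                                   y = rep(60, 20)))
  frames <- fr$frames
  frames[[10]] <- matrix(0.5, 120, 160)  # uniform frame: detection fails
  tr <- track_frames(frames, scale = 0.2, origin = c(80, 60), max_gap = 3)
  expect_equal(tr$quality[10], "interpolated")
  expect_equal(tr$h_deg[10], (tr$h_deg[9] + tr$h_deg[11]) / 2, tolerance = 1e-9)
  expect_equal(diff(tr$time_s)[1], diff(tr$time_s)[9])  # grid stays uniform

  for (i in 5:15) frames[[i]] <- matrix(0.5, 120, 160)
  tr2 <- track_frames(frames, scale = 0.2, origin = c(80, 60), max_gap = 3)
  expect_true(all(tr2$quality[5:15] == "artifact"))

  all_bad <- replicate(5, matrix(0.5, 120, 160), simplify = FALSE)
  expect_error(track_frames(all_bad), class = "povar_tracking_failed")
  expect_error(track_frames(list(matrix(0, 2, 2))), class = "povar_invalid_parameter")
})
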