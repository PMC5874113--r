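test_that("motion parameters are validated", {
  expect_error(motion_params(0, 10), "positive")
  expect_error(motion_params(30, -1), "non-negative")
  expect_error(motion_params(30, 10, pause_s = -0.1), "non-negative")
  # 30 bpm -> T = 2 s, so pauses of 1 s each leave no time to move
  expect_error(motion_params(30, 10, pause_s = 1), "exceed")
  expect_s3_class(motion_params(30, 50, 0.33), "motion_params")
})

test_that("modified sine hits the cycle landmarks", {
  p <- motion_params(30, 50, 0.33)   # T = 2 s, r = 0.67 s
  r <- (p$period_s - 2 * p$pause_s) / 2
  expect_equal(modified_sine_displacement(0, p), 0)
  expect_equal(modified_sine_displacement(r, p), 50)
  expect_equal(modified_sine_displacement(r / 2, p), 50 * sin(pi / 4),
               tolerance = 1e-12)
  # plateaus: full inhale for pause_s, full exhale closes the cycle
  expect_equal(modified_sine_displacement(r + 0.2, p), 50)
  expect_equal(modified_sine_displacement(2 * r + p$pause_s + 0.1, p), 0)
  expect_error(modified_sine_displacement(-0.1, p), "non-negative")
})

test_that("modified sine is periodic, bounded and continuous", {
  for (p in list(motion_params(30, 50, 0.33), motion_params(12, 20, 0),
                 motion_params(25, 60, 0.1, phase_offset_s = 0.4))) {
    t <- seq(0, 2 * p$period_s, by = 1e-3)
    d <- modified_sine_displacement(t, p)
    expect_true(all(d >= 0 & d <= p$amplitude_mm + 1e-12))
    expect_equal(modified_sine_displacement(t, p),
                 modified_sine_displacement(t + p$period_s, p),
                 tolerance = 1e-9)
    # no jump exceeds the motion-law slope bound over one grid step
    r <- (p$period_s - 2 * p$pause_s) / 2
    slope <- p$amplitude_mm * pi / (2 * r)
    expect_lt(max(abs(diff(d))), slope * 1e-3 * 1.01)
  }
})

test_that("numerical peak speed matches the closed form", {
  # pause 0: quarter-sine peak speed is a*pi/(2r) with r = T/2
  p <- motion_params(30, 50, 0)
  t <- seq(0, p$period_s, by = 1e-5)
  v_num <- max(abs(diff(modified_sine_displacement(t, p)))) / 1e-5
  expect_equal(v_num, p$amplitude_mm * pi / p$period_s, tolerance = 1e-3)
  # with pauses the envelope bound 2fa * (pi/2)/(1 - 2p/T) holds
  p2 <- motion_params(30, 50, 0.33)
  t2 <- seq(0, p2$period_s, by = 1e-5)
  v2 <- max(abs(diff(modified_sine_displacement(t2, p2)))) / 1e-5
  bound <- peak_speed(p2) * (pi / 2) / (1 - 2 * p2$pause_s / p2$period_s)
  expect_lte(v2, bound * 1.001)
})

test_that("design speed 2fa reproduces the worst-case bound", {
  expect_equal(peak_speed(motion_params(30, 50)), 50)  # 5 cm/s
  expect_equal(peak_speed(motion_params(30, 0)), 0)
  expect_equal(peak_speed(motion_params(15, 20)), 10)
})

test_that("stepper quantization rounds to the nearest step", {
  expect_identical(quantize_motion(c(0.3, 1.07), 0), c(0.3, 1.07))
  expect_equal(quantize_motion(1.07, 0.5), 1.0)
  grid <- seq(0, 50, by = 0.0173)
  for (s in c(0.05, 0.2, 1.3)) {
    q <- quantize_motion(grid, s)
    expect_lte(max(abs(q - grid)), s / 2 + 1e-12)
    expect_true(all(abs(q / s - round(q / s)) < 1e-9))
  }
  expect_error(quantize_motion(1, -1), "non-negative")
})

test_that("piecewise patterns are continuous and rest at baseline", {
  pat <- motion_pattern(motion_params(12, 20, 0.33, n_cycles = 2),
                        motion_params(25, 5, 0.33, n_cycles = 4))
  expect_equal(pattern_duration(pat), 2 * 5 + 4 * 2.4)
  t <- seq(0, pattern_duration(pat) + 2, by = 1e-3)
  d <- motion_displacement(t, pat)
  expect_lt(max(abs(diff(d))), 20 * pi / (2 * 2.17) * 1e-3 * 1.05)
  expect_true(all(d[t > pattern_duration(pat)] == 0))
  # segment boundaries sit at whole cycles, so both sides are at baseline
  expect_equal(motion_displacement(10 - 1e-9, pat), 0, tolerance = 1e-6)
})
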