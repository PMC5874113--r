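# Build a single-marker mm trace directly from a motion law (no tracking),
# with displacement on the AP axis and 0 on SI.
law_trace <- function(motion, fps, duration_s, marker_id = 1, si = NULL) {
  n <- round(fps * duration_s)
  t <- (seq_len(n) - 1) / fps
  ap <- motion_displacement(t, motion)
  data.frame(frame = seq_len(n), time_s = t, marker_id = marker_id,
             SI = if (is.null(si)) rep(0, n) else si, AP = ap,
             status = "ok")
}

law_truth <- function(trace) trace[, c("frame", "time_s", "marker_id", "SI", "AP")]

test_that("baseline re-referencing subtracts the window mean", {
  tr <- law_trace(motion_params(30, 10, 0.33), 30, 4)
  const <- tr; const$AP <- 2.5
  out <- displacement_from_baseline(const, 1:10)
  expect_true(all(out$AP == 0))
  step <- tr; step$AP <- c(0, rep(3, nrow(tr) - 1))
  out2 <- displacement_from_baseline(step, 1L)
  expect_equal(out2$AP[-1], rep(3, nrow(tr) - 1))
  expect_error(displacement_from_baseline(tr, 10000L), "outside")
})

test_that("gating alerts flag threshold crossings and can latch", {
  tr <- law_trace(motion_params(30, 4, 0.33), 30, 4)
  expect_false(any(gate_signal(tr, gate_config(c(AP = 5, SI = 5)))))
  one <- tr; one$AP[50] <- 6
  a <- gate_signal(one, gate_config(c(AP = 5, SI = 5)))
  expect_identical(sum(a), 1L)
  expect_identical(which(a), 50L)
  al <- gate_signal(one, gate_config(c(AP = 5, SI = 5), latch = TRUE))
  expect_true(all(al[50:length(al)]))
  expect_false(any(al[1:49]))
  expect_error(gate_signal(tr, gate_config(c(SI = 5))), "every observed axis")
})

test_that("alert fraction matches closed-form cycle crossing times", {
  p <- motion_params(15, 20, 0.33)          # T = 4 s
  fps <- 30
  tr <- law_trace(p, fps, p$period_s)       # exactly one cycle
  frac <- mean(gate_signal(tr, gate_config(c(AP = 5, SI = 5))))
  r <- (p$period_s - 2 * p$pause_s) / 2
  t1 <- (2 * r / pi) * asin(5 / 20)         # rise crossing of 5 mm
  frac_true <- (2 * (r - t1) + p$pause_s) / p$period_s
  expect_lt(abs(frac - frac_true), 2 / nrow(tr))
})

test_that("alert count is monotone non-increasing in the threshold", {
  tr <- law_trace(motion_params(12, 18, 0.2), 30, 10)
  counts <- vapply(seq(1, 20, by = 1), function(th)
    sum(gate_signal(tr, gate_config(c(AP = th, SI = th)))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("the modified-sine fit reproduces a noiseless trace exactly", {
  p <- motion_params(30, 25, 0.33)
  tr <- law_trace(p, 30, 8)
  fit <- fit_modified_sine(tr, p, axis = "AP")
  expect_true(fit$converged)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_lt(fit$rmse_mm, 1e-4)
  expect_error(fit_modified_sine(law_trace(p, 30, 3), p, axis = "AP"),
               "two cycles")
})

test_that("fit recovers frequency and amplitude within 1 % across the grid", {
  for (f in c(10, 20, 30)) for (a in c(2, 50)) for (ps in c(0, 0.33)) {
    p <- motion_params(f, a, ps)
    tr <- law_trace(p, 30, 2.5 * p$period_s)
    init <- motion_params(f * 1.08, a * 0.9, max(ps, 0.05))
    fit <- fit_modified_sine(tr, init, axis = "AP", n_phase_starts = 6)
    expect_lt(abs(fit$params$frequency_bpm - f) / f, 0.01)
    expect_lt(abs(fit$params$amplitude_mm - a) / a, 0.01)
  }
})

test_that("error statistics summarize computed-minus-true per axis", {
  tr <- law_trace(motion_params(30, 10, 0.33), 30, 4)
  es <- error_statistics(tr, law_truth(tr))
  expect_true(all(abs(es$stats$mean) < 1e-12))
  expect_true(all(es$stats$max_abs < 1e-12))
  off <- tr; off$AP <- off$AP + 0.2
  es2 <- error_statistics(off, law_truth(tr))
  ap <- es2$stats[es2$stats$axis == "AP", ]
  expect_equal(ap$mean, 0.2); expect_equal(ap$sd, 0)
  # white noise of known SD is estimated within 15 % at n >= 600
  set.seed(9)
  n600 <- law_trace(motion_params(30, 10, 0.33), 30, 20)
  noisy <- n600; noisy$AP <- noisy$AP + rnorm(nrow(n600), sd = 0.05)
  es3 <- error_statistics(noisy, law_truth(n600))
  sd_hat <- es3$stats$sd[es3$stats$axis == "AP"]
  expect_lt(abs(sd_hat - 0.05) / 0.05, 0.15)
  bad <- tr; bad$time_s <- bad$time_s + 0.01
  expect_error(error_statistics(bad, law_truth(tr)), "timestamps")
})

test_that("inter-marker discrepancy is the per-frame spread", {
  t1 <- law_trace(motion_params(15, 10, 0.33), 30, 8, marker_id = 1)
  t2 <- law_trace(motion_params(15, 10, 0.33), 30, 8, marker_id = 2)
  both <- rbind(t1, t2)
  d0 <- multi_marker_discrepancy(both, "AP")
  expect_equal(d0$max_mm, 0)
  t2b <- t2; t2b$AP <- t2b$AP + 4
  d4 <- multi_marker_discrepancy(rbind(t1, t2b), "AP")
  expect_true(all(abs(d4$per_frame$range_mm - 4) < 1e-12))
  expect_equal(d4$max_mm, 4)
  expect_error(multi_marker_discrepancy(t1, "AP"), "two markers")
})

test_that("amplitude-scaled markers reach the closed-form max discrepancy", {
  p <- motion_params(15, 10, 0.33)
  tr <- rbind(
    law_trace(p, 30, 8, marker_id = 1),
    transform(law_trace(p, 30, 8, marker_id = 2), AP = AP * 1.2),
    transform(law_trace(p, 30, 8, marker_id = 3), AP = AP * 1.4))
  d <- multi_marker_discrepancy(tr, "AP")
  expect_equal(d$max_mm, 14 - 10, tolerance = 1e-9)  # max(a_i) - min(a_i)
  # permutation invariance
  perm <- tr[sample(nrow(tr)), ]
  expect_equal(multi_marker_discrepancy(perm, "AP")$max_mm, d$max_mm)
})

test_that("failure events follow the drift and step-discrepancy criteria", {
  p <- motion_params(30, 10, 0.33)
  tr <- law_trace(p, 30, 4)
  tru <- law_truth(tr)
  expect_identical(nrow(detect_failures(tr, tru)), 0L)
  # gradual 1.2 mm drift over 100 frames: one drift event, no step events
  drift <- tr
  drift$AP[21:120] <- drift$AP[21:120] + seq(0.012, 1.2, length.out = 100)
  ev <- detect_failures(drift, tru)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$type, "drift")
  expect_identical(ev$start_frame, 21L + match(TRUE, seq(0.012, 1.2, length.out = 100) > 1) - 1L)
  # single-frame 0.6 mm deviation: one step-discrepancy event
  blip <- tr; blip$AP[60] <- blip$AP[60] + 0.6
  ev2 <- detect_failures(blip, tru)
  expect_identical(nrow(ev2), 1L)
  expect_identical(ev2$type, "step")
  expect_identical(ev2$start_frame, 60L)
  # live mode (no ground truth) uses the speed-envelope surrogate
  expect_error(detect_failures(tr, NULL), "envelope")
  ev3 <- detect_failures(blip, NULL,
                         envelope_mm_per_frame = 1.5 * peak_speed(p) / 30)
  expect_identical(unique(ev3$type), "jump")
})
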