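test_that("identical frames give zero flow", {
  f <- texture_frame(texture_fun(1), 64, 64)
  r <- lk_step(f, f, c(32, 32))
  expect_true(r$converged)
  expect_equal(r$flow, c(0, 0), tolerance = 1e-6)
})

test_that("integer translations are recovered to 0.05 px", {
  tex <- texture_fun(2)
  f1 <- texture_frame(tex, 96, 96)
  cfg <- track_config(n_levels = 3)
  for (shift in list(c(3, -2), c(1, 0), c(-4, 5))) {
    f2 <- texture_frame(tex, 96, 96, dx = shift[1], dy = shift[2])
    res <- track_sequence(list(f1, f2),
                          data.frame(marker_id = 1, x_px = 48, y_px = 48),
                          cfg)
    flow <- c(res$points$x[2, 1] - 48, res$points$y[2, 1] - 48)
    expect_lt(max(abs(flow - shift)), 0.05)
  }
})

test_that("sub-pixel shifts are recovered to 0.1 px", {
  tex <- texture_fun(4)
  f1 <- texture_frame(tex, 64, 64)
  f2 <- texture_frame(tex, 64, 64, dx = 0.5)
  r <- lk_step(f1, f2, c(32, 32))
  expect_true(r$converged)
  expect_lt(abs(r$flow[1] - 0.5), 0.1)
  expect_lt(abs(r$flow[2]), 0.1)
})

test_that("coarse-to-fine succeeds where single-level tracking fails", {
  tex <- texture_fun(6, detail = 2.5)     # fine texture: 12 px >> wavelength
  f1 <- texture_frame(tex, 128, 128)
  f2 <- texture_frame(tex, 128, 128, dx = 12)
  init <- data.frame(marker_id = 1, x_px = 64, y_px = 64)
  multi <- track_sequence(list(f1, f2), init, track_config(n_levels = 3))
  err_multi <- abs(multi$points$x[2, 1] - 64 - 12)
  single <- track_sequence(list(f1, f2), init, track_config(n_levels = 1))
  err_single <- abs(single$points$x[2, 1] - 64 - 12)
  expect_lt(err_multi, 0.1)
  expect_true(is.na(err_single) || err_single > 1)
})

test_that("degenerate patches are refused (min-eigenvalue guard)", {
  flat <- matrix(0.5, 64, 64)
  r <- lk_step(flat, flat, c(32, 32))
  expect_identical(r$status, "singular")
  expect_false(r$converged)
  # pure 1-D gradient: aperture problem, tensor is rank deficient
  ramp <- outer(rep(1, 64), seq_len(64)) / 64
  r2 <- lk_step(ramp, ramp, c(32, 32))
  expect_identical(r2$status, "singular")
})

test_that("points leaving the frame are marked lost and stay lost", {
  tex <- texture_fun(8)
  frames <- lapply(0:6, function(k) texture_frame(tex, 64, 64, dx = 8 * k))
  res <- track_sequence(frames, data.frame(marker_id = 1, x_px = 40, y_px = 32),
                        track_config(n_levels = 2))
  st <- res$points$status[, 1]
  expect_true("lost" %in% st)
  first_lost <- match("lost", st)
  expect_true(all(st[first_lost:length(st)] == "lost"))
  expect_true(res$tracking_failed)
  expect_true(all(is.na(res$points$x[first_lost:length(st), 1])))
})

test_that("forward-then-reverse tracking returns to the start (round trip)", {
  sc <- small_square_scene(noise_sd = 0.01)
  s <- render_sequence(sc, motion_params(30, 15, 0.33), 30, 1, seed = 5)
  f1 <- s$frames[[1L]]
  ft <- select_features(f1, detect_markers(f1))
  fwd <- track_sequence(s$frames, ft)
  n <- length(s$frames)
  back_init <- data.frame(marker_id = ft$marker_id,
                          x_px = fwd$points$x[n, ], y_px = fwd$points$y[n, ])
  bwd <- track_sequence(rev(s$frames), back_init)
  expect_true(all(fwd$points$status == "ok"))
  expect_true(all(bwd$points$status == "ok"))
  dx <- bwd$points$x[n, ] - ft$x_px
  dy <- bwd$points$y[n, ] - ft$y_px
  expect_lt(max(abs(c(dx, dy))), 0.2)
})

test_that("static scenes track with sub-0.05 px jitter and no failures", {
  sc <- small_square_scene(noise_sd = 0)
  s <- render_sequence(sc, motion_params(30, 0), 30, 0.5, seed = 2)
  run <- run_tracking(s$frames)
  tr <- run$tracking$traces
  expect_true(all(tr$status == "ok"))
  expect_lt(max(abs(tr$x_px - tr$x_px[1])), 0.05)
  expect_lt(max(abs(tr$y_px - tr$y_px[1])), 0.05)
  mm <- traces_to_mm(run$tracking, camera_model(10))
  ev <- detect_failures(mm, truth = s$truth, camera = camera_model(10))
  expect_identical(nrow(ev), 0L)
})
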