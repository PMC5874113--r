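test_that("scene invariants are enforced", {
  expect_error(phantom_scene(c(100, 100), 10,
                             list(marker_spec(c(50, 50), 0.3))),
               "4 px")
  expect_error(phantom_scene(c(100, 100), -1,
                             list(marker_spec(c(50, 50), 5))))
  expect_s3_class(small_square_scene(), "phantom_scene")
})

test_that("zero amplitude gives identical frames and constant truth", {
  sc <- small_square_scene(noise_sd = 0)
  seq0 <- render_sequence(sc, motion_params(30, 0), fps = 10,
                          duration_s = 1, seed = 3)
  expect_length(seq0$frames, 10L)
  for (f in seq0$frames[-1L]) expect_identical(f, seq0$frames[[1L]])
  expect_true(all(seq0$truth$disp_mm == 0))
  expect_true(all(seq0$truth$y_px == 60))
})

test_that("frame and ground-truth bookkeeping is exact", {
  sc <- small_square_scene(noise_sd = 0.01)
  src <- phantom_frame_source(sc, motion_params(30, 15, 0.33),
                              fps = 30, duration_s = 40, seed = 0)
  expect_identical(src$n_frames, 1200L)
  expect_identical(nrow(src$truth), 1200L)
  expect_equal(src$timestamps_s, (0:1199) / 30)
  expect_true(all(diff(src$truth$time_s) > 0))
})

test_that("rendering is bit-reproducible for a fixed seed", {
  sc <- small_square_scene(noise_sd = 0.05)
  a <- render_sequence(sc, motion_params(30, 10, 0.33), 15, 1, seed = 42)
  b <- render_sequence(sc, motion_params(30, 10, 0.33), 15, 1, seed = 42)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth, b$truth)
  c_ <- render_sequence(sc, motion_params(30, 10, 0.33), 15, 1, seed = 43)
  expect_false(identical(a$frames, c_$frames))
  # frames are independent of access order
  src <- phantom_frame_source(sc, motion_params(30, 10, 0.33), 15, 1, 42)
  f7 <- src$get_frame(7)
  invisible(src$get_frame(2))
  expect_identical(src$get_frame(7), f7)
  expect_identical(f7, a$frames[[7L]])
})

test_that("rendered disc centroid matches ground truth (centroid oracle)", {
  sc <- phantom_scene(c(120, 160), 10,
                      list(marker_spec(c(60.3, 40.7), 3, "disc")),
                      noise_sd = 0)
  seq0 <- render_sequence(sc, motion_params(30, 5, 0.33), 20, 1, seed = 1)
  for (i in c(1L, 8L, 15L)) {
    f <- seq0$frames[[i]]
    tru <- seq0$truth[seq0$truth$frame == i, ]
    w <- f - sc$background_intensity      # background-free intensity mass
    w[w < 1e-6] <- 0
    cx <- sum(col(f) * w) / sum(w)
    cy <- sum(row(f) * w) / sum(w)
    expect_lt(abs(cx - tru$x_px), 0.05)
    expect_lt(abs(cy - tru$y_px), 0.05)
  }
})

test_that("a marker leaving the field of view is an error unless allowed", {
  sc <- small_square_scene(noise_sd = 0)        # 320 px tall, 150 px travel ok
  expect_error(phantom_frame_source(sc, motion_params(30, 30, 0.33), 30, 2, 0),
               "field of view")
  sc2 <- phantom_scene(c(200, 320), 10,
                       list(marker_spec(c(100, 60), 8, "square")),
                       noise_sd = 0, allow_exit = TRUE)
  expect_s3_class(phantom_frame_source(sc2, motion_params(30, 30, 0.33),
                                       30, 2, 0),
                  "frame_source")
})

test_that("illumination drift scales frames multiplicatively", {
  sc <- phantom_scene(c(64, 64), 10, list(marker_spec(c(32, 32), 2)),
                      noise_sd = 0,
                      illumination_drift = function(i) 1 - 0.01 * (i - 1))
  s <- render_sequence(sc, motion_params(30, 0), 10, 0.5, seed = 0)
  expect_equal(s$frames[[3L]], s$frames[[1L]] * 0.98, tolerance = 1e-12)
})
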