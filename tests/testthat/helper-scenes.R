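# Shared fixtures: all synthetic, built in code.

# Smooth band-limited texture defined analytically, so it can be sampled at
# arbitrary (sub-pixel) offsets exactly. `detail` scales the spatial
# frequencies.
texture_fun <- function(seed = 1, n_waves = 8, detail = 1) {
  set.seed(seed)
  amp <- runif(n_waves, 0.05, 0.12)
  kx <- runif(n_waves, 0.05, 0.25) * detail
  ky <- runif(n_waves, 0.05, 0.25) * detail
  ph <- runif(n_waves, 0, 2 * pi)
  function(x, y) {
    v <- 0.5
    for (i in seq_len(n_waves))
      v <- v + amp[i] * sin(kx[i] * x + ky[i] * y + ph[i])
    v
  }
}

# Sample a texture function on an integer grid, optionally shifted: pixel
# (row i, col j) takes the value f(j - dx, i - dy), i.e. the pattern moves
# by (+dx, +dy) in image coordinates.
texture_frame <- function(f, width, height, dx = 0, dy = 0) {
  outer(seq_len(height), seq_len(width),
        function(i, j) f(j - dx, i - dy))
}

# Naive double-loop structure-tensor oracle (independent of the package's
# integral-image path): per-pixel central differences with border
# replication, summed explicitly.
brute_structure_tensor <- function(frame, p, w) {
  h <- nrow(frame); wd <- ncol(frame)
  gxx <- gxy <- gyy <- 0
  for (dy in -w:w) for (dx in -w:w) {
    x <- p[1] + dx; y <- p[2] + dy
    ix <- (frame[y, min(x + 1, wd)] - frame[y, max(x - 1, 1)]) / 2
    iy <- (frame[min(y + 1, h), x] - frame[max(y - 1, 1), x]) / 2
    gxx <- gxx + ix * ix; gxy <- gxy + ix * iy; gyy <- gyy + iy * iy
  }
  matrix(c(gxx, gxy, gxy, gyy), 2, 2)
}

# Small single-square-marker scene used across tests.
small_square_scene <- function(noise_sd = 0, amplitude_scale = 1,
                               size_px = c(200, 320)) {
  phantom_scene(size_px, 10,
                list(marker_spec(c(100, 60), 8, "square",
                                 amplitude_scale = amplitude_scale)),
                noise_sd = noise_sd)
}

# Reference bench scenario shared by the acceptance checks: 30 bpm, 330 ms
# pauses, 25 mm amplitude, 10 px/mm, 640 x 480 px, 30 fps, 60 s, mild noise.
# Tracked once per test run and memoized.
.ref_env <- new.env(parent = emptyenv())
reference_phantom_run <- function() {
  if (!is.null(.ref_env$report)) return(.ref_env$report)
  scene <- phantom_scene(c(640, 480), 10,
                         list(marker_spec(c(320, 120), 10, "square")),
                         noise_sd = 0.02)
  params <- motion_params(30, 25, 0.33)
  .ref_env$report <- run_phantom_validation(
    scene, params, fps = 30, duration_s = 60,
    camera = camera_model(10), seed = 0)
  .ref_env$report
}
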