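# Digital twin of the mechanical thorax phantom: renders high-contrast
# fiducial markers moving along the modified-sine law on a flat background,
# with anti-aliased rasterization, optional illumination drift and additive
# Gaussian intensity noise, plus frame-exact ground truth.
#
# Frames are numeric matrices in [0, 1]; row = image y (down), column =
# image x (right); the centre of pixel (i, j) is at x = j, y = i (1-based).

#' Marker specification for the phantom scene
#'
#' @param centre_px Marker centre `c(x, y)` in pixels at baseline
#'   (displacement 0).
#' @param size_mm Marker size in mm: side length for squares, diameter for
#'   discs. Markers on patients are centimetric, so 10 mm is typical.
#' @param shape `"square"` or `"disc"`. The physical markers are flat
#'   paper/plastic patches; squares offer strong corners, discs a symmetric
#'   blob.
#' @param intensity Foreground intensity in `[0, 1]`.
#' @param amplitude_scale Per-marker multiplier on the scene motion (1 =
#'   follow the motion law exactly). Lets one scene carry markers of
#'   different excursion, as different spots on a breast move by different
#'   amounts.
#' @return A `marker_spec` list.
#' @export
marker_spec <- function(centre_px, size_mm, shape = c("square", "disc"),
                        intensity = 0.85, amplitude_scale = 1) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(centre_px), length(centre_px) == 2L,
            is.numeric(size_mm), length(size_mm) == 1L, size_mm > 0,
            is.numeric(intensity), length(intensity) == 1L,
            intensity >= 0, intensity <= 1,
            is.numeric(amplitude_scale), length(amplitude_scale) == 1L,
            amplitude_scale >= 0)
  structure(list(centre_px = as.numeric(centre_px), size_mm = size_mm,
                 shape = shape, intensity = intensity,
                 amplitude_scale = amplitude_scale),
            class = "marker_spec")
}

#' Phantom scene description
#'
#' Geometry, optics and noise model of a synthetic marker video: which
#' markers exist, at what pixel scale they are imaged, and how the frames are
#' degraded.
#'
#' @param image_size_px `c(width, height)` of the rendered frames in pixels.
#' @param pixel_scale_px_per_mm Image resolution at the marker plane
#'   (pixels per millimetre); 10 px/mm matches a long-lens camera at
#'   treatment distance.
#' @param markers List of [marker_spec()] objects (a single spec is
#'   accepted).
#' @param background_intensity Background grey level in `[0, 1]`.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   (image units); frames are clipped back to `[0, 1]`.
#' @param illumination_drift Optional per-frame multiplicative illumination
#'   factor: a function of the frame index or a numeric vector; `NULL` means
#'   constant illumination.
#' @param motion_axis Image axis along which the phantom moves: `"y"`
#'   (default, vertical = anteroposterior for a lateral camera) or `"x"`.
#' @param motion_sign +1 moves towards larger pixel coordinates, -1 the
#'   opposite way.
#' @param allow_exit If `FALSE` (default), rendering stops with an error when
#'   a marker would leave the field of view.
#' @return A `phantom_scene` object.
#' @export
phantom_scene <- function(image_size_px, pixel_scale_px_per_mm, markers,
                          background_intensity = 0.15, noise_sd = 0.02,
                          illumination_drift = NULL,
                          motion_axis = c("y", "x"), motion_sign = 1,
                          allow_exit = FALSE) {
  motion_axis <- match.arg(motion_axis)
  if (inherits(markers, "marker_spec")) markers <- list(markers)
  stopifnot(is.numeric(image_size_px), length(image_size_px) == 2L,
            all(image_size_px >= 16),
            is.numeric(pixel_scale_px_per_mm),
            length(pixel_scale_px_per_mm) == 1L, pixel_scale_px_per_mm > 0,
            length(markers) >= 1L,
            background_intensity >= 0, background_intensity <= 1,
            is.numeric(noise_sd), noise_sd >= 0,
            motion_sign %in% c(-1, 1))
  for (m in markers) {
    if (!inherits(m, "marker_spec")) stop("markers must be 'marker_spec' objects")
    if (m$size_mm * pixel_scale_px_per_mm < 4)
      stop("marker smaller than 4 px at this pixel scale cannot be resolved")
  }
  structure(
    list(image_size_px = as.integer(image_size_px),
         pixel_scale_px_per_mm = pixel_scale_px_per_mm,
         markers = markers,
         background_intensity = background_intensity,
         noise_sd = noise_sd,
         illumination_drift = illumination_drift,
         motion_axis = motion_axis,
         motion_sign = motion_sign,
         allow_exit = allow_exit),
    class = "phantom_scene")
}

# Fractional overlap of pixels [z - 0.5, z + 0.5] with interval [lo, hi].
.interval_coverage <- function(z, lo, hi) {
  pmax(0, pmin(z + 0.5, hi) - pmax(z - 0.5, lo))
}

# Paint one marker onto `img` (modified in place by value semantics) with its
# centre at (cx, cy) in pixels. Squares use exact separable area coverage;
# discs are rasterized with 4x4 supersampling per pixel.
.paint_marker <- function(img, marker, cx, cy, pixel_scale) {
  h <- nrow(img); w <- ncol(img)
  half <- marker$size_mm * pixel_scale / 2
  x0 <- max(1L, floor(cx - half - 1)); x1 <- min(w, ceiling(cx + half + 1))
  y0 <- max(1L, floor(cy - half - 1)); y1 <- min(h, ceiling(cy + half + 1))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  if (marker$shape == "square") {
    cov <- outer(.interval_coverage(ys, cy - half, cy + half),
                 .interval_coverage(xs, cx - half, cx + half))
  } else {
    off <- c(-0.375, -0.125, 0.125, 0.375)
    sx <- rep(xs, each = length(off)) + off
    sy <- rep(ys, each = length(off)) + off
    dx2 <- (sx - cx)^2
    dy2 <- (sy - cy)^2
    inside <- outer(dy2, dx2, "+") <= half^2
    # average the 4x4 subsamples back to pixel resolution
    grp_y <- rep(seq_along(ys), each = length(off))
    grp_x <- rep(seq_along(xs), each = length(off))
    cov <- rowsum(t(rowsum(inside + 0, grp_y)), grp_x)
    cov <- t(cov) / 16
  }
  patch <- img[ys, xs, drop = FALSE]
  img[ys, xs] <- patch * (1 - cov) + marker$intensity * cov
  img
}

# Deterministic (noise-free, unit-illumination) frame at given per-marker
# centres, a list of c(x, y).
.render_clean <- function(scene, centres) {
  img <- matrix(scene$background_intensity,
                nrow = scene$image_size_px[2L], ncol = scene$image_size_px[1L])
  for (i in seq_along(scene$markers)) {
    img <- .paint_marker(img, scene$markers[[i]],
                         centres[[i]][1L], centres[[i]][2L],
                         scene$pixel_scale_px_per_mm)
  }
  img
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so frame rendering never perturbs user code.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

.illumination_factor <- function(scene, frame_idx) {
  dr <- scene$illumination_drift
  if (is.null(dr)) return(1)
  if (is.function(dr)) return(dr(frame_idx))
  dr[[min(frame_idx, length(dr))]]
}

#' Lazy phantom video with frame-exact ground truth
#'
#' Builds a frame source for a phantom recording: ground truth (true sub-pixel
#' marker centres and millimetre displacement for every frame) is computed
#' up front, while frames are rendered on demand so long sequences never need
#' to be held in memory at once. Rendering is bit-reproducible: frame `i`
#' depends only on the scene, the motion law and `seed + i`, regardless of
#' the order in which frames are requested.
#'
#' @param scene A [phantom_scene()].
#' @param motion A [motion_params()], [motion_pattern()] or `function(t)`
#'   giving displacement in mm.
#' @param fps Frame rate in Hz.
#' @param duration_s Recording length in seconds; `n_frames = round(fps *
#'   duration_s)` frames are produced at timestamps `(i - 1) / fps`.
#' @param seed Integer seed for the noise stream.
#' @param step_size_mm Optional stepper quantization applied to the true
#'   motion (see [quantize_motion()]); 0 disables it.
#' @return A `frame_source` object: fields `n_frames`, `fps`, `timestamps_s`,
#'   `get_frame(i)` and `truth` (data frame with one row per frame and
#'   marker: `frame`, `time_s`, `marker_id`, `disp_mm`, `x_px`, `y_px`).
#' @export
phantom_frame_source <- function(scene, motion, fps, duration_s, seed = 0,
                                 step_size_mm = 0) {
  stopifnot(inherits(scene, "phantom_scene"), fps > 0, duration_s > 0)
  n_frames <- as.integer(round(fps * duration_s))
  if (n_frames < 1) stop("duration too short for one frame at this fps")
  times <- (seq_len(n_frames) - 1) / fps
  disp <- quantize_motion(motion_displacement(times, motion), step_size_mm)

  nm <- length(scene$markers)
  w <- scene$image_size_px[1L]; h <- scene$image_size_px[2L]
  truth <- vector("list", nm)
  for (m in seq_len(nm)) {
    mk <- scene$markers[[m]]
    d <- disp * mk$amplitude_scale
    shift_px <- scene$motion_sign * d * scene$pixel_scale_px_per_mm
    x <- mk$centre_px[1L] + if (scene$motion_axis == "x") shift_px else 0
    y <- mk$centre_px[2L] + if (scene$motion_axis == "y") shift_px else 0
    half <- mk$size_mm * scene$pixel_scale_px_per_mm / 2
    if (!scene$allow_exit &&
        (any(x - half < 1) || any(x + half > w) ||
         any(y - half < 1) || any(y + half > h)))
      stop(sprintf("marker %d leaves the field of view; enlarge the image or set allow_exit = TRUE", m))
    truth[[m]] <- data.frame(frame = seq_len(n_frames), time_s = times,
                             marker_id = m, disp_mm = d, x_px = x, y_px = y)
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$frame, truth$marker_id), , drop = FALSE]
  rownames(truth) <- NULL

  centres_at <- function(i) {
    rows <- truth[truth$frame == i, , drop = FALSE]
    lapply(seq_len(nrow(rows)), function(k) c(rows$x_px[k], rows$y_px[k]))
  }
  get_frame <- function(i) {
    stopifnot(i >= 1, i <= n_frames)
    img <- .render_clean(scene, centres_at(i)) * .illumination_factor(scene, i)
    if (scene$noise_sd > 0) {
      img <- img + .with_seed((seed + i) %% .Machine$integer.max, {
        matrix(stats::rnorm(h * w, sd = scene$noise_sd), nrow = h)
      })
    }
    pmin(pmax(img, 0), 1)
  }

  structure(list(n_frames = n_frames, fps = fps, timestamps_s = times,
                 get_frame = get_frame, truth = truth, scene = scene,
                 seed = seed),
            class = "frame_source")
}

#' Render a phantom sequence into memory
#'
#' Materializes all frames of a [phantom_frame_source()]. Convenient for
#' short sequences and tests; for minutes-long recordings prefer passing the
#' frame source itself to [track_sequence()], which streams frames.
#'
#' @inheritParams phantom_frame_source
#' @return A list with `frames` (list of matrices), `timestamps_s`, `truth`,
#'   `fps` and `seed`.
#' @export
render_sequence <- function(scene, motion, fps, duration_s, seed = 0,
                            step_size_mm = 0) {
  src <- phantom_frame_source(scene, motion, fps, duration_s, seed,
                              step_size_mm)
  frames <- lapply(seq_len(src$n_frames), src$get_frame)
  list(frames = frames, timestamps_s = src$timestamps_s, truth = src$truth,
       fps = fps, seed = seed)
}

#' Wrap in-memory frames as a frame source
#'
#' @param frames List of numeric matrices (identical dimensions).
#' @param fps Frame rate used to derive timestamps.
#' @param timestamps_s Optional explicit timestamps (overrides `fps` spacing).
#' @return A `frame_source` object without ground truth.
#' @export
frame_source <- function(frames, fps = 30, timestamps_s = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  if (is.null(timestamps_s)) timestamps_s <- (seq_along(frames) - 1) / fps
  stopifnot(length(timestamps_s) == length(frames),
            all(diff(timestamps_s) > 0))
  structure(list(n_frames = length(frames), fps = fps,
                 timestamps_s = timestamps_s,
                 get_frame = function(i) frames[[i]],
                 truth = NULL),
            class = "frame_source")
}

#' @export
print.frame_source <- function(x, ...) {
  f1 <- x$get_frame(1)
  cat(sprintf("Frame source: %d frames of %d x %d px at %.4g fps%s\n",
              x$n_frames, ncol(f1), nrow(f1), x$fps,
              if (is.null(x$truth)) "" else " (with ground truth)"))
  invisible(x)
}

as_frame_source <- function(frames, fps = 30) {
  if (inherits(frames, "frame_source")) return(frames)
  if (is.list(frames)) return(frame_source(frames, fps))
  stop("'frames' must be a frame_source or a list of matrices")
}
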