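# Pyramidal Lucas-Kanade optical flow. The single-level step iteratively
# solves the 2x2 normal equations G v = b with spatial gradients taken on
# the previous frame (classical LK) and the temporal difference resampled
# by bilinear interpolation at the current estimate; the pyramidal tracker
# chains the step coarse-to-fine and propagates each point's previous flow
# as the initial guess, so per-frame motion well beyond the window size
# remains trackable.

# Core single-level solve. prevI/Ix/Iy are the previous frame and its
# gradient images at this level; p is the point in this level's coordinates.
# Returns list(flow, residual, converged, status) with status one of
# "ok", "singular", "oob".
.lk_core <- function(prevI, Ix, Iy, nextI, p, guess, window, max_iter, eps,
                     min_eig) {
  offs <- -window:window
  ox <- rep(offs, each = 2L * window + 1L)
  oy <- rep(offs, times = 2L * window + 1L)
  xs <- p[1L] + ox; ys <- p[2L] + oy
  dimb <- dim(prevI)
  if (!.window_inside(dimb, p, window + 1))
    return(list(flow = guess, residual = NA_real_, converged = FALSE,
                status = "oob"))
  Tw <- .bilinear(prevI, xs, ys)
  gx <- .bilinear(Ix, xs, ys)
  gy <- .bilinear(Iy, xs, ys)
  g11 <- sum(gx * gx); g12 <- sum(gx * gy); g22 <- sum(gy * gy)
  n_px <- length(gx)
  half_tr <- (g11 + g22) / 2
  lam_min <- half_tr - sqrt(max(half_tr^2 - (g11 * g22 - g12^2), 0))
  if (lam_min / n_px < min_eig)
    return(list(flow = guess, residual = NA_real_, converged = FALSE,
                status = "singular"))
  det_g <- g11 * g22 - g12^2
  v <- guess
  converged <- FALSE
  dI <- NULL
  for (it in seq_len(max_iter)) {
    px <- p[1L] + v[1L]; py <- p[2L] + v[2L]
    if (!.window_inside(dim(nextI), c(px, py), window + 1))
      return(list(flow = v, residual = NA_real_, converged = FALSE,
                  status = "oob"))
    J <- .bilinear(nextI, px + ox, py + oy)
    dI <- Tw - J
    b1 <- sum(dI * gx); b2 <- sum(dI * gy)
    dv <- c(g22 * b1 - g12 * b2, g11 * b2 - g12 * b1) / det_g
    v <- v + dv
    if (sqrt(sum(dv^2)) < eps) { converged <- TRUE; break }
  }
  list(flow = v, residual = sqrt(mean(dI^2)), converged = converged,
       status = "ok")
}

#' Single-level Lucas-Kanade step
#'
#' Estimates the optical flow of one point between two frames on a single
#' pyramid level by iteratively solving the Lucas-Kanade normal equations
#' over a `(2*window+1)^2` patch. Spatial gradients are computed on `prev`
#' only; the patch of `next` is resampled bilinearly at the current flow
#' estimate each iteration. The solve is declared non-converged when the
#' normalized minimum eigenvalue of the gradient matrix falls below
#' `min_eig` (featureless or aperture-limited patch).
#'
#' @param prev,next_ Previous and next frames (numeric matrices of equal
#'   size).
#' @param p Point `c(x, y)` (sub-pixel) in `prev`.
#' @param guess Initial flow estimate `c(dx, dy)` in pixels.
#' @param window Patch half-width (default 7: a 15x15 window).
#' @param max_iter Iteration cap.
#' @param eps Convergence threshold on the update norm, in pixels.
#' @param min_eig Threshold on `lambda_min(G) / n_pixels`. The default
#'   1e-6 is calibrated to unit-range intensities (an ideal corner scores
#'   around 1e-3 per pixel, a flat or 1-D patch exactly 0).
#' @return List with `flow` (c(dx, dy)), `residual` (RMS intensity
#'   difference at the solution), `converged`, and `status`
#'   (`"ok"`, `"singular"`, `"oob"`).
#' @export
lk_step <- function(prev, next_, p, guess = c(0, 0), window = 7,
                    max_iter = 30, eps = 0.01, min_eig = 1e-6) {
  .check_frame(prev); .check_frame(next_)
  stopifnot(all(dim(prev) == dim(next_)), length(p) == 2L,
            length(guess) == 2L, window >= 1, max_iter >= 1, eps > 0)
  if (!.window_inside(dim(prev), p, window + 1) ||
      !.window_inside(dim(next_), p + guess, window + 1))
    stop("window does not fit inside the frames at this point")
  g <- .gradients(prev)
  .lk_core(prev, g$Ix, g$Iy, next_, p, guess, window, max_iter, eps, min_eig)
}

#' Tracking configuration
#'
#' @param n_levels Pyramid depth (coarse-to-fine).
#' @param window Lucas-Kanade patch half-width in pixels.
#' @param max_iter Per-level iteration cap.
#' @param eps Per-level convergence threshold in pixels.
#' @param min_eig Normalized minimum-eigenvalue threshold below which a patch
#'   is considered untrackable.
#' @param use_prior_flow Use each point's previous inter-frame flow as the
#'   initial guess for the next frame pair (breathing motion is smooth, so
#'   this extends the trackable speed range well beyond the window size).
#' @return A `track_config` list.
#' @export
track_config <- function(n_levels = 3, window = 7, max_iter = 30,
                         eps = 0.01, min_eig = 1e-6, use_prior_flow = TRUE) {
  stopifnot(n_levels >= 1, window >= 1, max_iter >= 1, eps > 0, min_eig >= 0)
  structure(list(n_levels = n_levels, window = window, max_iter = max_iter,
                 eps = eps, min_eig = min_eig,
                 use_prior_flow = isTRUE(use_prior_flow)),
            class = "track_config")
}

# One coarse-to-fine flow estimate for a single point between two pyramids.
# Coarse levels only refine the guess: a point whose window does not fit (or
# whose patch degenerates) at a decimated level skips that level; only the
# full-resolution solve decides success or failure.
.pyramidal_flow <- function(pyr_prev, grads_prev, pyr_next, p, guess, cfg) {
  L <- cfg$n_levels
  v <- guess / 2^(L - 1)
  for (lev in seq(L, 2L, length.out = max(L - 1L, 0L))) {
    pl <- .to_level(p, lev)
    res <- .lk_core(pyr_prev$levels[[lev]], grads_prev[[lev]]$Ix,
                    grads_prev[[lev]]$Iy, pyr_next$levels[[lev]],
                    pl, v, cfg$window, cfg$max_iter, cfg$eps, cfg$min_eig)
    v <- if (res$status == "ok") res$flow * 2 else v * 2
  }
  .lk_core(pyr_prev$levels[[1L]], grads_prev[[1L]]$Ix, grads_prev[[1L]]$Iy,
           pyr_next$levels[[1L]], p, v, cfg$window, cfg$max_iter, cfg$eps,
           cfg$min_eig)
}

#' Track feature points through an image sequence
#'
#' Runs pyramidal Lucas-Kanade frame to frame for every initial feature
#' point. A point becomes `"lost"` when its window leaves the frame and
#' `"failed"` when the local solve degenerates (near-singular gradient
#' matrix) or stops converging; in either case it is not re-acquired. The
#' per-marker trajectory is the median over that marker's surviving feature
#' points, which is robust to a single drifting corner.
#'
#' @param frames A `frame_source` (see [phantom_frame_source()],
#'   [frame_source()], [read_frames()]) or a list of matrices.
#' @param initial Data frame of starting points from [select_features()]
#'   (columns `marker_id`, `x_px`, `y_px`).
#' @param config A [track_config()].
#' @param fps Frame rate, used only when `frames` is a bare list.
#' @return A `tracking_result` list: `points` (per-point position arrays and
#'   status matrix), `traces` (data frame `frame`, `time_s`, `marker_id`,
#'   `x_px`, `y_px`, `n_points`, `status`), `tracking_failed` flag (TRUE
#'   when every point was lost before the final frame), `config`.
#' @export
track_sequence <- function(frames, initial, config = track_config(),
                           fps = 30) {
  src <- as_frame_source(frames, fps)
  stopifnot(inherits(config, "track_config"), nrow(initial) >= 1L)
  n <- src$n_frames
  if (n < 2L) stop("at least two frames are required for tracking")
  np <- nrow(initial)

  pos_x <- matrix(NA_real_, n, np); pos_y <- matrix(NA_real_, n, np)
  status <- matrix("ok", n, np)
  pos_x[1L, ] <- initial$x_px; pos_y[1L, ] <- initial$y_px
  flow_prev <- matrix(0, 2L, np)
  active <- rep(TRUE, np)

  prep <- function(frame) {
    pyr <- build_pyramid(frame, config$n_levels)
    list(pyr = pyr, grads = lapply(pyr$levels, .gradients))
  }
  prev <- prep(src$get_frame(1L))

  for (i in 2L:n) {
    nxt_frame <- src$get_frame(i)
    pyr_next <- build_pyramid(nxt_frame, config$n_levels)
    for (j in seq_len(np)) {
      if (!active[j]) { status[i, j] <- status[i - 1L, j]; next }
      p <- c(pos_x[i - 1L, j], pos_y[i - 1L, j])
      guess <- if (config$use_prior_flow) flow_prev[, j] else c(0, 0)
      res <- .pyramidal_flow(prev$pyr, prev$grads, pyr_next, p, guess, config)
      if (res$status == "oob") {
        status[i, j] <- "lost"; active[j] <- FALSE
      } else if (res$status == "singular" || !res$converged) {
        status[i, j] <- "failed"; active[j] <- FALSE
      } else {
        pos_x[i, j] <- p[1L] + res$flow[1L]
        pos_y[i, j] <- p[2L] + res$flow[2L]
        flow_prev[, j] <- res$flow
      }
    }
    prev <- list(pyr = pyr_next, grads = lapply(pyr_next$levels, .gradients))
  }

  marker_ids <- sort(unique(initial$marker_id))
  traces <- vector("list", length(marker_ids))
  for (k in seq_along(marker_ids)) {
    cols <- which(initial$marker_id == marker_ids[k])
    # trace = baseline reference point + median per-point displacement, so
    # that losing a feature point cannot shift the reported position
    ref_x <- stats::median(pos_x[1L, cols])
    ref_y <- stats::median(pos_y[1L, cols])
    mx <- my <- numeric(n); npts <- integer(n); st <- character(n)
    for (i in seq_len(n)) {
      ok <- cols[status[i, cols] == "ok"]
      npts[i] <- length(ok)
      if (length(ok) > 0L) {
        mx[i] <- ref_x + stats::median(pos_x[i, ok] - pos_x[1L, ok])
        my[i] <- ref_y + stats::median(pos_y[i, ok] - pos_y[1L, ok])
        st[i] <- "ok"
      } else {
        mx[i] <- NA_real_; my[i] <- NA_real_
        st[i] <- if (any(status[i, cols] == "lost")) "lost" else "failed"
      }
    }
    traces[[k]] <- data.frame(frame = seq_len(n), time_s = src$timestamps_s,
                              marker_id = marker_ids[k], x_px = mx, y_px = my,
                              n_points = npts, status = st)
  }
  traces <- do.call(rbind, traces)
  rownames(traces) <- NULL
  tracking_failed <- !all(traces$status[traces$frame == n] == "ok")
  structure(list(points = list(x = pos_x, y = pos_y, status = status,
                               marker_id = initial$marker_id),
                 traces = traces, tracking_failed = tracking_failed,
                 config = config),
            class = "tracking_result")
}

#' @export
print.tracking_result <- function(x, ...) {
  n <- max(x$traces$frame)
  nm <- length(unique(x$traces$marker_id))
  cat(sprintf("Tracked %d marker(s), %d feature point(s) over %d frames%s\n",
              nm, length(x$points$marker_id), n,
              if (x$tracking_failed) " [TRACKING FAILED]" else ""))
  invisible(x)
}
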