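# Turning pixel trajectories into clinical outputs: millimetre displacement
# traces, amplitude-gating alerts, modified-sine fit statistics, error
# statistics against ground truth, inter-marker discrepancy and failure
# events.
#
# A millimetre trace is a data frame with columns `frame`, `time_s`,
# `marker_id` and one column per observed anatomical axis ("AP", "SI",
# "LR"), holding displacement from baseline in mm.

.axis_cols <- function(trace) intersect(c("AP", "SI", "LR"), names(trace))

#' Convert pixel traces to millimetre displacement traces
#'
#' Undistorts the per-frame marker positions (when the camera model carries
#' distortion coefficients), subtracts each marker's baseline position (mean
#' over `baseline_frames`) and converts the pixel displacement to mm in
#' anatomical axes via the camera model.
#'
#' @param traces_px Pixel traces from [track_sequence()] (`$traces`).
#' @param camera A [camera_model()].
#' @param baseline_frames Frame indices defining the reference position;
#'   default the first frame.
#' @return Millimetre trace data frame (`frame`, `time_s`, `marker_id`,
#'   anatomical axis columns, `status`).
#' @export
traces_to_mm <- function(traces_px, camera, baseline_frames = 1L) {
  if (inherits(traces_px, "tracking_result")) traces_px <- traces_px$traces
  stopifnot(inherits(camera, "camera_model"), length(baseline_frames) >= 1L)
  out <- list()
  for (id in sort(unique(traces_px$marker_id))) {
    tr <- traces_px[traces_px$marker_id == id, , drop = FALSE]
    pos <- cbind(tr$x_px, tr$y_px)
    ok <- tr$status == "ok" & !is.na(tr$x_px)
    if (camera$k1 != 0 || camera$k2 != 0)
      pos[ok, ] <- undistort(pos[ok, , drop = FALSE], camera)
    base_rows <- which(tr$frame %in% baseline_frames & ok)
    if (length(base_rows) == 0L)
      stop(sprintf("marker %s has no valid samples in the baseline window", id))
    base <- colMeans(pos[base_rows, , drop = FALSE])
    mm <- px_to_mm(sweep(pos, 2L, base), camera)
    df <- data.frame(frame = tr$frame, time_s = tr$time_s, marker_id = id)
    df[[colnames(mm)[1L]]] <- mm[, 1L]
    df[[colnames(mm)[2L]]] <- mm[, 2L]
    df$status <- tr$status
    out[[length(out) + 1L]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Re-reference a trace to a baseline window
#'
#' Subtracts, per marker and axis, the mean displacement over the baseline
#' window, so the trace reads as distance from the (possibly new) initial
#' location.
#'
#' @param trace Millimetre trace data frame.
#' @param baseline_frames Frame indices of the baseline window (non-empty,
#'   present in the trace).
#' @return The re-referenced trace.
#' @export
displacement_from_baseline <- function(trace, baseline_frames = 1L) {
  axes <- .axis_cols(trace)
  stopifnot(length(axes) >= 1L, length(baseline_frames) >= 1L)
  if (!all(baseline_frames %in% trace$frame))
    stop("baseline window is outside the trace")
  for (id in unique(trace$marker_id)) {
    sel <- trace$marker_id == id
    base_sel <- sel & trace$frame %in% baseline_frames
    for (ax in axes) {
      base <- mean(trace[[ax]][base_sel], na.rm = TRUE)
      if (!is.finite(base)) stop("baseline window has no valid samples")
      trace[[ax]][sel] <- trace[[ax]][sel] - base
    }
  }
  trace
}

#' Gating configuration
#'
#' @param thresholds_mm Named numeric vector of per-axis amplitude
#'   thresholds in mm (names among "AP", "SI", "LR"), or a single unnamed
#'   value applied to every observed axis.
#' @param latch If `TRUE`, the alert stays on once raised.
#' @return A `gate_config` list.
#' @export
gate_config <- function(thresholds_mm, latch = FALSE) {
  stopifnot(is.numeric(thresholds_mm), length(thresholds_mm) >= 1L,
            all(thresholds_mm > 0))
  structure(list(thresholds_mm = thresholds_mm, latch = isTRUE(latch)),
            class = "gate_config")
}

#' Amplitude-gating alerts
#'
#' Flags every sample at which any axis' absolute displacement exceeds its
#' threshold — the visual alert a gating display would raise. With
#' `latch = TRUE` the alert persists after the first excursion.
#'
#' @param trace Millimetre trace data frame (single marker or several; the
#'   alert is evaluated per row).
#' @param config A [gate_config()].
#' @return Logical vector, one element per trace row.
#' @export
gate_signal <- function(trace, config) {
  stopifnot(inherits(config, "gate_config"))
  axes <- .axis_cols(trace)
  stopifnot(length(axes) >= 1L)
  th <- config$thresholds_mm
  if (is.null(names(th))) {
    stopifnot(length(th) == 1L)
    th <- stats::setNames(rep(th, length(axes)), axes)
  }
  if (!all(axes %in% names(th)))
    stop("a threshold must be set for every observed axis")
  alert <- rep(FALSE, nrow(trace))
  for (ax in axes)
    alert <- alert | (!is.na(trace[[ax]]) & abs(trace[[ax]]) > th[[ax]])
  if (config$latch) alert <- cumsum(alert) > 0
  alert
}

#' Fit the modified-sine motion law to a trace
#'
#' Least-squares fit of the phantom motion law (free parameters: amplitude,
#' frequency, pause duration, phase offset and a constant baseline offset)
#' to one axis of a displacement trace. The objective is minimized by
#' Nelder-Mead from a grid of phase starts (the phase dimension is
#' multimodal), and the best start is polished by Levenberg-Marquardt
#' (`minpack.lm`). Fit quality is summarized by the coefficient of
#' determination `R^2 = 1 - SS_res/SS_tot` (SS_tot about the trace mean) and
#' the RMSE in mm.
#'
#' @param trace Millimetre trace data frame for a single marker.
#' @param init A [motion_params()] guess; the trace must span at least two
#'   cycles of the initial period.
#' @param axis Axis column to fit; defaults to the first observed axis.
#' @param n_phase_starts Number of phase starts spread over one period.
#' @return List with `params` (fitted [motion_params()]), `offset_mm`,
#'   `r_squared`, `rmse_mm`, `fitted` (model values at the trace times),
#'   `converged`, `message`.
#' @export
fit_modified_sine <- function(trace, init, axis = NULL, n_phase_starts = 8L) {
  stopifnot(inherits(init, "motion_params"))
  axes <- .axis_cols(trace)
  if (is.null(axis)) axis <- axes[1L]
  stopifnot(axis %in% axes)
  keep <- !is.na(trace[[axis]])
  t <- trace$time_s[keep]; y <- trace[[axis]][keep]
  if (length(t) < 10L) stop("too few valid samples to fit")
  span <- diff(range(t)) + stats::median(diff(t))   # duration covered
  if (span < 2 * init$period_s)
    stop("trace must span at least two cycles of the initial period")

  model_at <- function(theta, t) {
    a <- abs(theta[1L]); f <- abs(theta[2L]); p <- abs(theta[3L])
    if (f <= 0 || 60 / f <= 2 * p) return(rep(1e6, length(t)))
    pr <- motion_params(f, a, p, phase_offset_s = theta[4L] %% (60 / f))
    modified_sine_displacement(t, pr) + theta[5L]
  }
  sse <- function(theta) {
    r <- y - model_at(theta, t)
    sum(r * r)
  }

  best <- NULL
  phases <- init$phase_offset_s +
    init$period_s * (seq_len(n_phase_starts) - 1L) / n_phase_starts
  for (ph in phases) {
    th0 <- c(init$amplitude_mm, init$frequency_bpm, init$pause_s, ph, 0)
    opt <- stats::optim(th0, sse, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  polished <- tryCatch({
    fit <- minpack.lm::nls.lm(best$par,
                              fn = function(theta) y - model_at(theta, t),
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    if (sum(fit$fvec^2) < best$value)
      list(par = fit$par, value = sum(fit$fvec^2), convergence = 0L)
    else best
  }, error = function(e) best)
  # a second simplex pass from the polished optimum settles kink-adjacent cases
  refined <- stats::optim(polished$par, sse, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-14))
  if (refined$value < polished$value) polished <- refined

  theta <- polished$par
  fitted <- model_at(theta, t)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  f_hat <- abs(theta[2L])
  params <- motion_params(f_hat, abs(theta[1L]), abs(theta[3L]),
                          phase_offset_s = theta[4L] %% (60 / f_hat))
  converged <- is.finite(polished$value) &&
    (is.null(polished$convergence) || polished$convergence %in% c(0L, 1L, 10L))
  full_fitted <- rep(NA_real_, nrow(trace))
  full_fitted[keep] <- fitted
  list(params = params, offset_mm = theta[5L],
       r_squared = 1 - ss_res / ss_tot,
       rmse_mm = sqrt(ss_res / length(y)),
       fitted = full_fitted, converged = converged,
       message = if (converged) "ok" else
         "optimizer did not report convergence; inspect rmse_mm and r_squared")
}

# Align a single-marker mm trace with phantom ground truth and return the
# per-frame error vectors (computed - true) on the observed axes.
.trace_truth_errors <- function(trace, truth, camera) {
  stopifnot(length(unique(trace$marker_id)) == 1L)
  tru <- truth[truth$marker_id == trace$marker_id[1L], , drop = FALSE]
  m <- match(trace$frame, tru$frame)
  if (any(is.na(m)))
    stop("ground truth does not cover every trace frame")
  tru <- tru[m, , drop = FALSE]
  if (max(abs(tru$time_s - trace$time_s)) > 1e-9)
    stop("trace and ground-truth timestamps do not match")
  axes <- intersect(.axis_cols(trace), .axis_cols(tru))
  if (length(axes) == 0L)
    stop("trace and ground truth share no anatomical axis")
  err <- matrix(NA_real_, nrow(trace), length(axes),
                dimnames = list(NULL, axes))
  for (ax in axes) err[, ax] <- trace[[ax]] - tru[[ax]]
  err
}

#' Per-axis error statistics against ground truth
#'
#' Computes `computed - true` displacement per sample and axis, and
#' summarizes it (mean, SD, min, max, mean of |error|, max of |error|), all
#' in mm. Trace and ground truth must share timestamps.
#'
#' @param trace Millimetre trace for one marker.
#' @param truth Ground-truth data frame with `frame`, `time_s`, `marker_id`
#'   and either matching axis columns or `disp_mm` mapped via `camera`.
#' @param camera Optional [camera_model()]; required when `truth` carries
#'   only `disp_mm` + pixel positions (phantom output) so the displacement
#'   can be assigned to its anatomical axis.
#' @param motion_axis_image Image axis the phantom moved along (`"x"` or
#'   `"y"`), when `truth` is phantom output.
#' @return List with `errors` (per-sample matrix), `stats` (data frame per
#'   axis: mean, sd, min, max, mean_abs, max_abs), and `norm` (per-sample
#'   Euclidean error across axes).
#' @export
error_statistics <- function(trace, truth, camera = NULL,
                             motion_axis_image = "y") {
  truth <- normalize_truth(truth, camera, motion_axis_image)
  err <- .trace_truth_errors(trace, truth, camera)
  axes <- colnames(err)
  stats_df <- do.call(rbind, lapply(axes, function(ax) {
    e <- err[, ax]; e <- e[!is.na(e)]
    data.frame(axis = ax, mean = mean(e), sd = stats::sd(e),
               min = min(e), max = max(e),
               mean_abs = mean(abs(e)), max_abs = max(abs(e)))
  }))
  list(errors = err, stats = stats_df,
       norm = sqrt(rowSums(err^2)))
}

#' Express phantom ground truth in anatomical axes
#'
#' Phantom ground truth records displacement along the scene's motion axis
#' (`disp_mm`); this helper expands it to anatomical axis columns using the
#' camera's axis map, leaving the orthogonal axis at its true value of 0.
#' Ground truth that already has axis columns is returned unchanged.
#'
#' @param truth Ground-truth data frame.
#' @param camera A [camera_model()] (required for phantom-format truth).
#' @param motion_axis_image `"x"` or `"y"`: image axis the phantom moved
#'   along.
#' @return Ground truth with `AP`/`SI`/`LR` columns as observed.
#' @export
normalize_truth <- function(truth, camera = NULL, motion_axis_image = "y") {
  if (any(c("AP", "SI", "LR") %in% names(truth))) return(truth)
  if (!"disp_mm" %in% names(truth))
    stop("ground truth needs anatomical axis columns or 'disp_mm'")
  if (is.null(camera)) stop("a camera model is required to map 'disp_mm' to axes")
  moving <- unname(camera$axis_map[[motion_axis_image]])
  other <- setdiff(unname(camera$axis_map), moving)
  truth[[moving]] <- truth$disp_mm * camera$axis_sign[[motion_axis_image]]
  truth[[other]] <- 0
  truth
}

#' Inter-marker discrepancy
#'
#' Per-frame spread (max minus min) of displacement across markers on one
#' axis, quantifying how differently distinct skin locations move; the
#' summary is the maximum spread over the recording. Permutation-invariant
#' in the markers.
#'
#' @param trace Millimetre trace with at least two markers on common frames.
#' @param axis Axis to compare (default first observed).
#' @return List with `per_frame` (data frame `frame`, `time_s`, `range_mm`)
#'   and `max_mm`.
#' @export
multi_marker_discrepancy <- function(trace, axis = NULL) {
  axes <- .axis_cols(trace)
  if (is.null(axis)) axis <- axes[1L]
  stopifnot(axis %in% axes)
  ids <- unique(trace$marker_id)
  if (length(ids) < 2L) stop("at least two markers are required")
  frames <- sort(unique(trace$frame))
  wide <- matrix(NA_real_, length(frames), length(ids))
  for (k in seq_along(ids)) {
    tr <- trace[trace$marker_id == ids[k], , drop = FALSE]
    wide[match(tr$frame, frames), k] <- tr[[axis]]
  }
  if (any(rowSums(!is.na(wide)) < length(ids)))
    stop("markers do not share common timestamps on every frame")
  rng <- apply(wide, 1L, function(v) max(v) - min(v))
  t_of <- trace$time_s[match(frames, trace$frame)]
  list(per_frame = data.frame(frame = frames, time_s = t_of, range_mm = rng),
       max_mm = max(rng))
}

#' Failure criteria for tracking validation
#'
#' Tracking counts as failed when the error versus the actual position
#' either accumulates beyond `max_drift_mm` (long-term drift) or jumps by
#' more than `max_step_discrepancy_mm` between two successive images.
#'
#' @param max_drift_mm Long-term drift bound (default 1 mm).
#' @param max_step_discrepancy_mm Successive-image discrepancy bound
#'   (default 0.5 mm).
#' @return A `failure_criteria` list.
#' @export
failure_criteria <- function(max_drift_mm = 1, max_step_discrepancy_mm = 0.5) {
  stopifnot(max_drift_mm > 0, max_step_discrepancy_mm > 0)
  structure(list(max_drift_mm = max_drift_mm,
                 max_step_discrepancy_mm = max_step_discrepancy_mm),
            class = "failure_criteria")
}

# Maximal runs of TRUE in a logical vector -> data.frame(start, end).
.runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Detect tracking-failure events
#'
#' With ground truth: a *drift* event is a maximal run of frames whose
#' absolute error (Euclidean across observed axes) exceeds the drift bound,
#' and a *step-discrepancy* event is a maximal run of frames where the error
#' changes by more than the step bound between successive images. Without
#' ground truth the step criterion degrades to a per-frame jump check
#' against a speed envelope (`envelope_mm_per_frame`), since the actual
#' position is unknown — a documented live-mode surrogate, not the phantom
#' criterion.
#'
#' @param trace Millimetre trace for one marker.
#' @param truth Ground truth (as in [error_statistics()]) or `NULL`.
#' @param criteria A [failure_criteria()].
#' @param camera,motion_axis_image Passed to [normalize_truth()] for
#'   phantom-format truth.
#' @param envelope_mm_per_frame Per-frame displacement bound used when
#'   `truth` is `NULL`; typically `peak_speed(params) / fps` times a safety
#'   margin.
#' @return Data frame of events: `type` (`"drift"`, `"step"`, `"jump"`,
#'   `"lost"`), `start_frame`, `end_frame`, `peak_mm`.
#' @export
detect_failures <- function(trace, truth = NULL,
                            criteria = failure_criteria(),
                            camera = NULL, motion_axis_image = "y",
                            envelope_mm_per_frame = NULL) {
  stopifnot(inherits(criteria, "failure_criteria"))
  events <- list()
  add <- function(type, runs, peak) {
    if (nrow(runs) == 0L) return()
    events[[length(events) + 1L]] <<- data.frame(
      type = type, start_frame = trace$frame[runs$start],
      end_frame = trace$frame[runs$end], peak_mm = peak(runs))
  }
  lost <- trace$status != "ok"
  if (any(lost)) {
    r <- .runs(lost)
    events[[length(events) + 1L]] <- data.frame(
      type = "lost", start_frame = trace$frame[r$start],
      end_frame = trace$frame[r$end], peak_mm = NA_real_)
  }
  if (!is.null(truth)) {
    truth <- normalize_truth(truth, camera, motion_axis_image)
    err <- .trace_truth_errors(trace, truth, camera)
    e_norm <- sqrt(rowSums(err^2))
    drift_bad <- !is.na(e_norm) & e_norm > criteria$max_drift_mm
    add("drift", .runs(drift_bad),
        function(r) vapply(seq_len(nrow(r)), function(i)
          max(e_norm[r$start[i]:r$end[i]]), 0))
    step <- sqrt(rowSums(apply(err, 2L, function(v) c(0, diff(v)))^2))
    step_bad <- !is.na(step) & step > criteria$max_step_discrepancy_mm
    add("step", .runs(step_bad),
        function(r) vapply(seq_len(nrow(r)), function(i)
          max(step[r$start[i]:r$end[i]]), 0))
  } else {
    if (is.null(envelope_mm_per_frame))
      stop("without ground truth, 'envelope_mm_per_frame' must be given")
    axes <- .axis_cols(trace)
    d <- sapply(axes, function(ax) c(0, diff(trace[[ax]])))
    jump <- sqrt(rowSums(matrix(d, ncol = length(axes))^2))
    jump_bad <- !is.na(jump) & jump > envelope_mm_per_frame
    add("jump", .runs(jump_bad),
        function(r) vapply(seq_len(nrow(r)), function(i)
          max(jump[r$start[i]:r$end[i]]), 0))
  }
  if (length(events) == 0L)
    return(data.frame(type = character(), start_frame = integer(),
                      end_frame = integer(), peak_mm = numeric()))
  ev <- do.call(rbind, events)
  ev[order(ev$start_frame), , drop = FALSE]
}
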