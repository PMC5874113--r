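# End-to-end pipelines: detection + feature selection + tracking on any
# frame source, and the full phantom validation loop that reproduces the
# bench experiment (render, track, compare to ground truth, fit the motion
# law, scan for failures).

#' Detect markers and track them through a sequence
#'
#' Runs the full chain on a frame source: marker detection on the first
#' frame, Shi-Tomasi feature initialization on each marker, then pyramidal
#' Lucas-Kanade tracking of every feature point.
#'
#' @param frames A `frame_source` or list of matrices.
#' @param detect A [detect_config()].
#' @param features A [feature_config()]; its `dilate_px` defaults to the
#'   tracker window.
#' @param track A [track_config()].
#' @param fps Frame rate when `frames` is a bare list.
#' @return List with `markers`, `features`, `tracking` (a
#'   [track_sequence()] result).
#' @export
run_tracking <- function(frames, detect = detect_config(),
                         features = feature_config(),
                         track = track_config(), fps = 30) {
  src <- as_frame_source(frames, fps)
  first <- src$get_frame(1L)
  markers <- detect_markers(first, detect)
  if (nrow(markers) == 0L)
    stop("no markers detected in the first frame")
  feats <- select_features(first, markers, features)
  if (nrow(feats) == 0L)
    stop("no trackable feature points found on the detected markers")
  tracking <- track_sequence(src, feats, track)
  list(markers = markers, features = feats, tracking = tracking)
}

#' Phantom validation run
#'
#' Renders a synthetic phantom recording, tracks it blind (the tracker never
#' sees the ground truth), converts the trajectories to millimetres and
#' compares them to the frame-exact truth: error statistics, modified-sine
#' fit quality, failure events per the drift / step-discrepancy criteria,
#' and (for multi-marker scenes) inter-marker discrepancy.
#'
#' @param scene A [phantom_scene()].
#' @param motion A [motion_params()] or [motion_pattern()].
#' @param fps Frame rate (Hz).
#' @param duration_s Recording length (s).
#' @param camera A [camera_model()]; its pixel scale should match the scene.
#' @param seed Seed for the rendering noise stream.
#' @param detect,features,track,criteria Stage configurations.
#' @param fit_axis Axis for the sine fit (default: the axis the phantom
#'   moves along).
#' @param do_fit Set `FALSE` to skip the sine fit (e.g. for piecewise
#'   patterns the single-cycle law cannot represent).
#' @return A `validation_report` list: `traces_mm`, `truth`, `error_stats`
#'   (per marker), `fit` (per marker or NULL), `failures` (per marker),
#'   `n_failure_events`, `discrepancy` (or NULL), `passed` (no failure
#'   events and all markers tracked to the final frame), plus the run
#'   metadata (`fps`, `duration_s`, `seed`, `n_frames`).
#' @export
run_phantom_validation <- function(scene, motion, fps, duration_s, camera,
                                   seed = 0, detect = detect_config(),
                                   features = feature_config(),
                                   track = track_config(),
                                   criteria = failure_criteria(),
                                   fit_axis = NULL, do_fit = TRUE) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(camera, "camera_model"))
  src <- phantom_frame_source(scene, motion, fps, duration_s, seed)
  run <- run_tracking(src, detect, features, track)
  traces_mm <- traces_to_mm(run$tracking, camera, baseline_frames = 1L)
  # truth displacement is relative to the baseline position, like the traces
  truth <- normalize_truth(src$truth, camera, scene$motion_axis)
  if (is.null(fit_axis))
    fit_axis <- unname(camera$axis_map[[scene$motion_axis]])

  ids <- sort(unique(traces_mm$marker_id))
  error_stats <- list(); fits <- list(); failures <- list()
  for (id in ids) {
    tr <- traces_mm[traces_mm$marker_id == id, , drop = FALSE]
    key <- as.character(id)
    error_stats[[key]] <- error_statistics(tr, truth, camera,
                                           scene$motion_axis)
    failures[[key]] <- detect_failures(tr, truth, criteria, camera,
                                       scene$motion_axis)
    if (do_fit && inherits(motion, "motion_params")) {
      fits[[key]] <- fit_modified_sine(tr, motion, axis = fit_axis)
    }
  }
  discrepancy <- if (length(ids) >= 2L)
    multi_marker_discrepancy(traces_mm, axis = fit_axis) else NULL
  n_events <- sum(vapply(failures, nrow, 0L))
  structure(
    list(markers = run$markers, features = run$features,
         tracking = run$tracking, traces_mm = traces_mm, truth = truth,
         error_stats = error_stats,
         fit = if (length(fits) > 0L) fits else NULL,
         failures = failures, n_failure_events = n_events,
         discrepancy = discrepancy,
         passed = n_events == 0L && !run$tracking$tracking_failed,
         fps = fps, duration_s = duration_s, seed = seed,
         n_frames = src$n_frames, fit_axis = fit_axis),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Phantom validation: %d frames at %g fps (%.3g s), seed %d\n",
              x$n_frames, x$fps, x$duration_s, x$seed))
  for (key in names(x$error_stats)) {
    es <- x$error_stats[[key]]
    cat(sprintf("  marker %s: mean |err| %.4f mm, max |err| %.4f mm\n",
                key, mean(es$norm, na.rm = TRUE), max(es$norm, na.rm = TRUE)))
    if (!is.null(x$fit[[key]]))
      cat(sprintf("            sine fit R^2 = %.5f, RMSE = %.4f mm\n",
                  x$fit[[key]]$r_squared, x$fit[[key]]$rmse_mm))
  }
  if (!is.null(x$discrepancy))
    cat(sprintf("  inter-marker discrepancy (max): %.3f mm\n",
                x$discrepancy$max_mm))
  cat(sprintf("  failure events: %d -> %s\n", x$n_failure_events,
              if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}

#' Flatten a validation report to key-value pairs
#'
#' @param report A `validation_report`.
#' @return Named list of scalars suitable for YAML/JSON serialization.
#' @export
report_summary <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  out <- list(n_frames = report$n_frames, fps = report$fps,
              duration_s = report$duration_s, seed = report$seed,
              n_markers = length(report$error_stats),
              n_failure_events = report$n_failure_events,
              passed = report$passed)
  for (key in names(report$error_stats)) {
    es <- report$error_stats[[key]]
    out[[paste0("marker_", key, "_mean_abs_error_mm")]] <-
      mean(es$norm, na.rm = TRUE)
    out[[paste0("marker_", key, "_max_abs_error_mm")]] <-
      max(es$norm, na.rm = TRUE)
    out[[paste0("marker_", key, "_sd_error_mm")]] <-
      stats::sd(es$norm, na.rm = TRUE)
    if (!is.null(report$fit[[key]])) {
      out[[paste0("marker_", key, "_fit_r_squared")]] <-
        report$fit[[key]]$r_squared
      out[[paste0("marker_", key, "_fit_rmse_mm")]] <-
        report$fit[[key]]$rmse_mm
    }
  }
  if (!is.null(report$discrepancy))
    out$max_intermarker_discrepancy_mm <- report$discrepancy$max_mm
  out
}
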