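# Operational I/O: image sequences in and traces / reports / plots out.
# The canonical video input is a directory of numbered PNG or TIFF frames;
# container video files can be hooked in through a reader plugin.

.luminance <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3L] >= 3L)
      return(0.2126 * arr[, , 1L] + 0.7152 * arr[, , 2L] + 0.0722 * arr[, , 3L])
    return(arr[, , 1L])
  }
  stop("unsupported image layout")
}

#' Read an image sequence as frames
#'
#' Reads a directory of PNG/TIFF frames (in lexical name order, so zero-pad
#' the indices) into a `frame_source` of single-channel intensities in
#' `[0, 1]`; RGB input is converted to luminance (Rec. 709 weights).
#' Timestamps come from a `timestamps.csv` sidecar (columns `frame`,
#' `time_s`) when present, otherwise from the constant frame rate `fps`.
#' Container video files are supported only through a `reader` plugin, a
#' `function(path)` returning a list of matrices.
#'
#' @param source Directory of image frames, or a video file if `reader` is
#'   given.
#' @param fps Frame rate used to derive timestamps without a sidecar.
#' @param reader Optional plugin for container video.
#' @return A `frame_source`.
#' @export
read_frames <- function(source, fps = 30, reader = NULL) {
  if (!file.exists(source))
    stop(sprintf("input '%s' does not exist", source))
  if (!dir.exists(source)) {
    if (is.null(reader))
      stop("container video requires a 'reader' plugin; supply frames as an image directory otherwise")
    return(frame_source(reader(source), fps))
  }
  files <- list.files(source, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L)
    stop(sprintf("no PNG/TIFF frames found in '%s'", source))
  files <- sort(files)
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    arr <- tryCatch({
      if (grepl("\\.png$", files[i], ignore.case = TRUE))
        png::readPNG(files[i])
      else tiff::readTIFF(files[i])
    }, error = function(e)
      stop(sprintf("frame %d ('%s') is unreadable: %s", i,
                   basename(files[i]), conditionMessage(e))))
    frames[[i]] <- .luminance(arr)
  }
  ts_file <- file.path(source, "timestamps.csv")
  timestamps <- if (file.exists(ts_file)) {
    ts <- utils::read.csv(ts_file)
    if (!all(c("frame", "time_s") %in% names(ts)) ||
        nrow(ts) != length(frames))
      stop("timestamps.csv must have columns frame, time_s and one row per frame")
    ts$time_s[order(ts$frame)]
  } else NULL
  frame_source(frames, fps, timestamps)
}

#' Write frames as a numbered PNG sequence
#'
#' @param frames List of matrices in `[0, 1]` or a `frame_source`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(frames, dir, prefix = "frame") {
  src <- as_frame_source(frames)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  width <- max(5L, nchar(as.character(src$n_frames)))
  paths <- character(src$n_frames)
  for (i in seq_len(src$n_frames)) {
    paths[i] <- file.path(dir, sprintf("%s_%0*d.png", prefix, width, i))
    png::writePNG(pmin(pmax(src$get_frame(i), 0), 1), paths[i])
  }
  invisible(paths)
}

#' Write ground truth as CSV
#'
#' @param truth Ground-truth data frame from a phantom source.
#' @param path Output CSV path.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' Write traces, report and plots for a run
#'
#' Emits the run's canonical outputs into `out_dir`:
#' * `traces.csv` — one row per frame and marker with pixel position,
#'   millimetre displacement per anatomical axis, tracking status and gating
#'   alert;
#' * `report.yaml` — machine-readable key-value summary (validation
#'   statistics when a [run_phantom_validation()] report is supplied);
#' * `traces_<axis>.png` — displacement-versus-time plots, one per axis
#'   (skipped with a warning if no PNG graphics device is available).
#'
#' @param traces_mm Millimetre trace data frame; pixel positions are joined
#'   in when `tracking` is given.
#' @param out_dir Output directory (created if missing).
#' @param tracking Optional [track_sequence()] result for pixel columns.
#' @param report Optional `validation_report` or named list for
#'   `report.yaml`.
#' @param gate Optional [gate_config()]; adds the `alert` column.
#' @param plots Emit plot files (default TRUE).
#' @return Invisibly, the paths written.
#' @export
write_traces <- function(traces_mm, out_dir, tracking = NULL, report = NULL,
                         gate = NULL, plots = TRUE) {
  stopifnot(nrow(traces_mm) >= 1L)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  axes <- .axis_cols(traces_mm)
  df <- traces_mm
  if (!is.null(tracking)) {
    px <- if (inherits(tracking, "tracking_result")) tracking$traces else tracking
    key <- paste(df$frame, df$marker_id)
    m <- match(key, paste(px$frame, px$marker_id))
    df$x_px <- px$x_px[m]; df$y_px <- px$y_px[m]
  }
  for (ax in c("AP", "SI", "LR"))
    if (!ax %in% names(df)) df[[ax]] <- NA_real_
  df$alert <- if (!is.null(gate)) gate_signal(traces_mm, gate) else FALSE
  cols <- c("frame", "time_s", "marker_id",
            intersect(c("x_px", "y_px"), names(df)),
            "AP", "SI", "LR", "status", "alert")
  df <- df[, cols]
  names(df)[names(df) %in% c("AP", "SI", "LR")] <-
    c("ap_mm", "si_mm", "lr_mm")
  paths <- file.path(out_dir, "traces.csv")
  utils::write.csv(df, paths, row.names = FALSE)

  if (!is.null(report)) {
    summ <- if (inherits(report, "validation_report")) report_summary(report)
            else report
    p <- file.path(out_dir, "report.yaml")
    yaml::write_yaml(summ, p)
    paths <- c(paths, p)
  }
  if (plots) {
    for (ax in axes) {
      p <- file.path(out_dir, sprintf("traces_%s.png", ax))
      ok <- tryCatch({
        grDevices::png(p, width = 1200, height = 500)
        ids <- unique(traces_mm$marker_id)
        cols_pal <- grDevices::hcl.colors(max(3L, length(ids)), "Dark 3")
        graphics::plot(NULL, xlim = range(traces_mm$time_s),
                       ylim = range(traces_mm[[ax]], na.rm = TRUE),
                       xlab = "time (s)", ylab = sprintf("%s (mm)", ax),
                       main = sprintf("%s displacement from baseline", ax))
        for (k in seq_along(ids)) {
          tr <- traces_mm[traces_mm$marker_id == ids[k], ]
          graphics::lines(tr$time_s, tr[[ax]], col = cols_pal[k])
        }
        graphics::legend("topright", legend = paste("marker", ids),
                         col = cols_pal[seq_along(ids)], lty = 1)
        grDevices::dev.off()
        TRUE
      }, error = function(e) {
        try(grDevices::dev.off(), silent = TRUE)
        warning(sprintf("could not write plot '%s': %s", p,
                        conditionMessage(e)))
        FALSE
      })
      if (ok) paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Read and validate a run configuration file
#'
#' YAML file mirroring the CLI flags: `input`, `fps`, `pixel_scale_px_per_mm`,
#' `k1`, `k2`, `principal_px`, `axis_map`, `axis_sign`, detection /
#' feature / tracking / gating settings, `out_dir`, `seed`. Unknown keys are
#' rejected so typos fail loudly before any computation.
#'
#' @param path YAML configuration file.
#' @return Named list of validated settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config '%s' does not exist", path))
  cfg <- yaml::read_yaml(path)
  known <- c("input", "fps", "pixel_scale_px_per_mm", "k1", "k2",
             "principal_px", "axis_map", "axis_sign",
             "threshold", "min_area_px", "max_area_px", "min_contrast",
             "polarity", "k", "feature_window", "min_separation_px",
             "n_levels", "window", "max_iter", "eps",
             "gate_thresholds_mm", "gate_latch",
             "max_drift_mm", "max_step_discrepancy_mm",
             "out_dir", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L)
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  if (!is.null(cfg$input) && !file.exists(cfg$input))
    stop(sprintf("config input '%s' is not resolvable", cfg$input))
  cfg
}
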