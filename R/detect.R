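# Fiducial marker detection in the first frame: intensity thresholding,
# connected-component labelling (EBImage), area/contrast filters and
# intensity-weighted sub-pixel centroids.

#' Detection configuration
#'
#' @param threshold `"otsu"` for automatic global thresholding, or a numeric
#'   intensity in `(0, 1)`.
#' @param min_area_px,max_area_px Connected-component area filter (pixels).
#' @param min_contrast Minimum mean foreground-minus-background intensity for
#'   a component to count as a marker.
#' @param polarity `"bright"` markers on a dark background (default) or
#'   `"dark"` markers on a bright background.
#' @return A `detect_config` list.
#' @export
detect_config <- function(threshold = "otsu", min_area_px = 25,
                          max_area_px = Inf, min_contrast = 0.1,
                          polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  if (!(identical(threshold, "otsu") ||
        (is.numeric(threshold) && length(threshold) == 1L &&
         threshold > 0 && threshold < 1)))
    stop("'threshold' must be \"otsu\" or a number in (0, 1)")
  stopifnot(min_area_px >= 1, max_area_px >= min_area_px, min_contrast >= 0)
  structure(list(threshold = threshold, min_area_px = min_area_px,
                 max_area_px = max_area_px, min_contrast = min_contrast,
                 polarity = polarity),
            class = "detect_config")
}

#' Detect fiducial markers in a frame
#'
#' Finds connected high-contrast regions: the frame is thresholded (Otsu or
#' fixed), connected components are labelled, and components passing the area
#' and contrast filters are reported with their intensity-weighted sub-pixel
#' centroid. Candidates are ordered by centroid (y, then x), so detection is
#' deterministic. An empty result is valid (no markers in view) and distinct
#' from an invalid-frame error.
#'
#' @param frame Numeric matrix in `[0, 1]`.
#' @param config A [detect_config()].
#' @return A data frame with one row per candidate: `marker_id`, `x_px`,
#'   `y_px` (sub-pixel centroid), `area_px`, bounding box `xmin`, `xmax`,
#'   `ymin`, `ymax`, and `contrast` (mean foreground minus mean background
#'   intensity).
#' @export
detect_markers <- function(frame, config = detect_config()) {
  .check_frame(frame)
  stopifnot(inherits(config, "detect_config"))
  work <- if (config$polarity == "dark") 1 - frame else frame
  th <- if (identical(config$threshold, "otsu")) {
    if (max(work) - min(work) < 1e-12) Inf   # flat frame: nothing to find
    else EBImage::otsu(EBImage::Image(t(work)), range = c(0, 1))
  } else config$threshold
  binary <- work > th
  empty <- data.frame(marker_id = integer(), x_px = numeric(),
                      y_px = numeric(), area_px = integer(),
                      xmin = integer(), xmax = integer(),
                      ymin = integer(), ymax = integer(),
                      contrast = numeric())
  if (!any(binary)) return(empty)
  # EBImage images are (x, y); transpose in and out of bwlabel
  labels <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(binary * 1)))))
  bg_mean <- mean(work[!binary])
  rows <- row(frame); cols <- col(frame)
  out <- list()
  for (lab in seq_len(max(labels))) {
    sel <- labels == lab
    area <- sum(sel)
    if (area < config$min_area_px || area > config$max_area_px) next
    wts <- work[sel]
    contrast <- mean(wts) - bg_mean
    if (contrast < config$min_contrast) next
    out[[length(out) + 1L]] <- data.frame(
      x_px = sum(cols[sel] * wts) / sum(wts),
      y_px = sum(rows[sel] * wts) / sum(wts),
      area_px = area,
      xmin = min(cols[sel]), xmax = max(cols[sel]),
      ymin = min(rows[sel]), ymax = max(rows[sel]),
      contrast = contrast)
  }
  if (length(out) == 0L) return(empty)
  out <- do.call(rbind, out)
  out <- out[order(out$y_px, out$x_px), , drop = FALSE]
  out <- cbind(marker_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
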