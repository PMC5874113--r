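# Shi-Tomasi corner initialization: structure tensor, minimum-eigenvalue
# score, response map and per-marker feature selection with non-maximum
# suppression.

#' Structure tensor at a pixel
#'
#' Windowed sum of gradient outer products
#' `G = sum_window [Ix^2, Ix*Iy; Ix*Iy, Iy^2]` over a `(2*window+1)^2`
#' neighbourhood, with gradients by central differences (border replication).
#' `G` is symmetric positive semi-definite; its minimum eigenvalue is the
#' Shi-Tomasi corner score.
#'
#' @param frame Numeric matrix.
#' @param p Integer pixel `c(x, y)`; the window must fit inside the frame.
#' @param window Window half-width (default 3, i.e. a 7x7 window).
#' @return A 2x2 symmetric matrix.
#' @export
structure_tensor <- function(frame, p, window = 3) {
  .check_frame(frame)
  stopifnot(length(p) == 2L, window >= 1)
  x <- p[1L]; y <- p[2L]
  if (x - window < 1 || x + window > ncol(frame) ||
      y - window < 1 || y + window > nrow(frame))
    stop("window does not fit inside the frame at this point")
  g <- .gradients(frame)
  ys <- (y - window):(y + window); xs <- (x - window):(x + window)
  Ix <- g$Ix[ys, xs]; Iy <- g$Iy[ys, xs]
  matrix(c(sum(Ix * Ix), sum(Ix * Iy), sum(Ix * Iy), sum(Iy * Iy)), 2L, 2L)
}

#' Shi-Tomasi corner score of a structure tensor
#'
#' Minimum eigenvalue of a 2x2 symmetric PSD matrix by the closed form
#' `trace/2 - sqrt((trace/2)^2 - det)`.
#'
#' @param G 2x2 symmetric matrix.
#' @return The minimum eigenvalue (non-negative up to rounding).
#' @export
shi_tomasi_score <- function(G) {
  stopifnot(is.matrix(G), all(dim(G) == 2L))
  half_tr <- (G[1L, 1L] + G[2L, 2L]) / 2
  half_tr - sqrt(max(half_tr^2 - (G[1L, 1L] * G[2L, 2L] - G[1L, 2L] * G[2L, 1L]), 0))
}

#' Shi-Tomasi response map
#'
#' Minimum eigenvalue of the structure tensor at every pixel, computed with
#' integral-image box sums. A border band of width `window + 1` is zeroed so
#' that only full windows compete in feature selection.
#'
#' @inheritParams structure_tensor
#' @return Matrix of scores, same dimensions as `frame`.
#' @export
shi_tomasi_response <- function(frame, window = 3) {
  .check_frame(frame)
  g <- .gradients(frame)
  A <- .box_sum(g$Ix * g$Ix, window)
  B <- .box_sum(g$Iy * g$Iy, window)
  C <- .box_sum(g$Ix * g$Iy, window)
  half_tr <- (A + B) / 2
  resp <- half_tr - sqrt(pmax(half_tr^2 - (A * B - C * C), 0))
  b <- window + 1L
  h <- nrow(resp); w <- ncol(resp)
  resp[c(seq_len(min(b, h)), seq.int(max(h - b + 1L, 1L), h)), ] <- 0
  resp[, c(seq_len(min(b, w)), seq.int(max(w - b + 1L, 1L), w))] <- 0
  resp
}

#' Feature-selection configuration
#'
#' @param k Maximum number of feature points kept per marker.
#' @param window Structure-tensor window half-width for corner scoring.
#'   Default 1 (a 3x3 window, the usual corner-detection block size): the
#'   response peak of an ideal corner sits roughly `window` pixels inside
#'   the corner, so small windows localize corners most faithfully.
#' @param min_separation_px Minimum distance between selected points
#'   (non-maximum suppression radius).
#' @param quality_rel Keep only points scoring at least this fraction of the
#'   best score within the marker's region.
#' @param min_score Absolute score floor; markers whose best point falls
#'   below it are flagged as feature-poor.
#' @param dilate_px How far beyond the marker bounding box to search,
#'   normally the tracker window half-width.
#' @return A `feature_config` list.
#' @export
feature_config <- function(k = 4, window = 1, min_separation_px = 8,
                           quality_rel = 0.2, min_score = 1e-4,
                           dilate_px = 7) {
  stopifnot(k >= 1, window >= 1, min_separation_px >= 0,
            quality_rel > 0, quality_rel <= 1, min_score >= 0, dilate_px >= 0)
  structure(list(k = k, window = window,
                 min_separation_px = min_separation_px,
                 quality_rel = quality_rel, min_score = min_score,
                 dilate_px = dilate_px),
            class = "feature_config")
}

#' Select trackable corner points on each marker
#'
#' Computes the Shi-Tomasi response once for the frame, then keeps, per
#' marker, up to `k` highest-scoring local maxima inside the marker's
#' bounding box (dilated by `dilate_px`), applying greedy non-maximum
#' suppression at `min_separation_px`. Ties are broken towards lower
#' `(y, x)`. A marker whose best score falls below `min_score` yields no
#' points and is reported in the `flagged_markers` attribute (with a
#' warning), never silently dropped.
#'
#' @param frame Numeric matrix.
#' @param markers Data frame from [detect_markers()].
#' @param config A [feature_config()].
#' @return Data frame with `marker_id`, `x_px`, `y_px`, `score`; attribute
#'   `flagged_markers` lists marker ids without usable features.
#' @export
select_features <- function(frame, markers, config = feature_config()) {
  .check_frame(frame)
  stopifnot(inherits(config, "feature_config"), nrow(markers) >= 1L)
  resp <- shi_tomasi_response(frame, config$window)
  h <- nrow(frame); w <- ncol(frame)
  out <- list(); flagged <- integer()
  for (i in seq_len(nrow(markers))) {
    mk <- markers[i, ]
    xs <- max(1L, mk$xmin - config$dilate_px):min(w, mk$xmax + config$dilate_px)
    ys <- max(1L, mk$ymin - config$dilate_px):min(h, mk$ymax + config$dilate_px)
    sub <- resp[ys, xs, drop = FALSE]
    best <- max(sub)
    if (best < config$min_score) {
      flagged <- c(flagged, mk$marker_id)
      next
    }
    keep <- which(sub >= config$quality_rel * best, arr.ind = TRUE)
    cand <- data.frame(x = xs[keep[, 2L]], y = ys[keep[, 1L]],
                       score = sub[keep])
    cand <- cand[order(-cand$score, cand$y, cand$x), , drop = FALSE]
    sel_x <- numeric(); sel_y <- numeric(); sel_s <- numeric()
    for (j in seq_len(nrow(cand))) {
      if (length(sel_x) >= config$k) break
      if (length(sel_x) > 0L) {
        d2 <- (sel_x - cand$x[j])^2 + (sel_y - cand$y[j])^2
        if (any(d2 < config$min_separation_px^2)) next
      }
      sel_x <- c(sel_x, cand$x[j]); sel_y <- c(sel_y, cand$y[j])
      sel_s <- c(sel_s, cand$score[j])
    }
    out[[length(out) + 1L]] <- data.frame(marker_id = mk$marker_id,
                                          x_px = sel_x, y_px = sel_y,
                                          score = sel_s)
  }
  if (length(flagged) > 0L)
    warning(sprintf("marker(s) %s have no feature point above the quality threshold",
                    paste(flagged, collapse = ", ")))
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(marker_id = integer(), x_px = numeric(), y_px = numeric(),
               score = numeric())
  rownames(res) <- NULL
  attr(res, "flagged_markers") <- flagged
  res
}
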