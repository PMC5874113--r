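# Pixel-to-millimetre calibration: a single-plane scalar pixel scale (the
# marker plane is close to fronto-parallel at treatment distance), an
# optional radial lens-distortion model, and the mapping from image axes to
# anatomical axes.

#' Camera model
#'
#' @param pixel_scale_px_per_mm Pixels per millimetre at the marker plane.
#' @param k1,k2 Radial distortion coefficients of the standard model
#'   `x_d = x_u * (1 + k1 r^2 + k2 r^4)` with `r` in pixels from the
#'   principal point. Default 0 (distortion correction is opt-in).
#' @param principal_px Principal point `c(x, y)` in pixels; required when
#'   `k1` or `k2` is non-zero.
#' @param axis_map Named character vector mapping image axes to anatomical
#'   axes, e.g. `c(x = "SI", y = "AP")` for a lateral camera or
#'   `c(x = "LR", y = "SI")` for a ceiling camera. The two anatomical axes
#'   must be distinct members of `AP`, `SI`, `LR`.
#' @param axis_sign Named numeric vector (`x`, `y`) of +-1 giving the
#'   anatomical direction of increasing pixel coordinate.
#' @return A `camera_model` object.
#' @export
camera_model <- function(pixel_scale_px_per_mm, k1 = 0, k2 = 0,
                         principal_px = NULL,
                         axis_map = c(x = "SI", y = "AP"),
                         axis_sign = c(x = 1, y = 1)) {
  stopifnot(is.numeric(pixel_scale_px_per_mm),
            length(pixel_scale_px_per_mm) == 1L, pixel_scale_px_per_mm > 0,
            is.numeric(k1), is.numeric(k2))
  axis_map <- axis_map[c("x", "y")]
  axis_sign <- axis_sign[c("x", "y")]
  if (any(is.na(axis_map)) || !all(axis_map %in% c("AP", "SI", "LR")) ||
      axis_map[1L] == axis_map[2L])
    stop("'axis_map' must map x and y to two distinct axes among AP, SI, LR")
  if (any(is.na(axis_sign)) || !all(axis_sign %in% c(-1, 1)))
    stop("'axis_sign' entries must be +1 or -1")
  if ((k1 != 0 || k2 != 0) &&
      (is.null(principal_px) || length(principal_px) != 2L))
    stop("'principal_px' is required when distortion coefficients are non-zero")
  structure(list(pixel_scale_px_per_mm = pixel_scale_px_per_mm,
                 k1 = k1, k2 = k2, principal_px = principal_px,
                 axis_map = axis_map, axis_sign = axis_sign),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("Camera model: %.4g px/mm; x -> %s%s, y -> %s%s; k1 = %g, k2 = %g\n",
              x$pixel_scale_px_per_mm,
              ifelse(x$axis_sign["x"] > 0, "+", "-"), x$axis_map["x"],
              ifelse(x$axis_sign["y"] > 0, "+", "-"), x$axis_map["y"],
              x$k1, x$k2))
  invisible(x)
}

.as_points <- function(p) {
  if (is.matrix(p)) { stopifnot(ncol(p) == 2L); return(p) }
  stopifnot(length(p) == 2L)
  matrix(p, ncol = 2L)
}

#' Apply radial lens distortion (forward model)
#'
#' @param p Undistorted point `c(x, y)` or an n x 2 matrix.
#' @param model A [camera_model()].
#' @return Distorted point(s), same shape as the input.
#' @export
distort <- function(p, model) {
  stopifnot(inherits(model, "camera_model"))
  pts <- .as_points(p)
  if (model$k1 == 0 && model$k2 == 0) return(if (is.matrix(p)) pts else drop(pts))
  rel <- sweep(pts, 2L, model$principal_px)
  r2 <- rowSums(rel^2)
  fac <- 1 + model$k1 * r2 + model$k2 * r2^2
  out <- sweep(rel * fac, 2L, model$principal_px, "+")
  if (is.matrix(p)) out else drop(out)
}

#' Undo radial lens distortion
#'
#' Inverts the radial model by fixed-point iteration
#' `x_u <- (x_d - c) / (1 + k1 r_u^2 + k2 r_u^4) + c` to 1e-8 px. With
#' `k1 = k2 = 0` this is the identity; the principal point always maps to
#' itself.
#'
#' @inheritParams distort
#' @param max_iter Iteration cap; non-convergence (extreme distortion) is an
#'   error.
#' @return Undistorted point(s), same shape as the input.
#' @export
undistort <- function(p, model, max_iter = 50) {
  stopifnot(inherits(model, "camera_model"))
  pts <- .as_points(p)
  if (any(!is.finite(pts))) stop("points must be finite")
  if (model$k1 == 0 && model$k2 == 0) return(if (is.matrix(p)) pts else drop(pts))
  rel_d <- sweep(pts, 2L, model$principal_px)
  rel_u <- rel_d
  for (it in seq_len(max_iter)) {
    r2 <- rowSums(rel_u^2)
    fac <- 1 + model$k1 * r2 + model$k2 * r2^2
    new_u <- rel_d / fac
    delta <- max(abs(new_u - rel_u))
    rel_u <- new_u
    if (delta < 1e-8) {
      out <- sweep(rel_u, 2L, model$principal_px, "+")
      return(if (is.matrix(p)) out else drop(out))
    }
  }
  stop("undistortion did not converge; distortion coefficients too extreme")
}

#' Convert a pixel displacement to millimetres in anatomical axes
#'
#' Divides by the pixel scale and applies the camera's image-axis to
#' anatomical-axis mapping with signs.
#'
#' @param displacement_px `c(dx, dy)` or an n x 2 matrix of pixel
#'   displacements.
#' @param model A [camera_model()].
#' @return Named vector (or n x 2 matrix with anatomical column names) in mm.
#' @export
px_to_mm <- function(displacement_px, model) {
  stopifnot(inherits(model, "camera_model"))
  pts <- .as_points(displacement_px)
  mm <- sweep(pts, 2L, unname(model$axis_sign), "*") / model$pixel_scale_px_per_mm
  colnames(mm) <- unname(model$axis_map)
  if (is.matrix(displacement_px)) mm else
    stats::setNames(drop(mm), unname(model$axis_map))
}

#' Convert an anatomical-axis displacement in mm to image pixels
#'
#' Exact inverse of [px_to_mm()].
#'
#' @param displacement_mm Named vector or n x 2 matrix with the camera's
#'   anatomical axis names (order-free when named).
#' @param model A [camera_model()].
#' @return `c(dx, dy)` pixel displacement (or n x 2 matrix).
#' @export
mm_to_px <- function(displacement_mm, model) {
  stopifnot(inherits(model, "camera_model"))
  pts <- .as_points(displacement_mm)
  nm <- if (is.matrix(displacement_mm)) colnames(displacement_mm) else
    names(displacement_mm)
  if (!is.null(nm)) {
    ord <- match(unname(model$axis_map), nm)
    if (any(is.na(ord))) stop("displacement axes do not match the camera's axis map")
    pts <- pts[, ord, drop = FALSE]
  }
  px <- sweep(pts, 2L, unname(model$axis_sign), "*") * model$pixel_scale_px_per_mm
  colnames(px) <- c("x", "y")
  if (is.matrix(displacement_mm)) px else stats::setNames(drop(px), c("x", "y"))
}

#' Calibrate the pixel scale from two markers at a known distance
#'
#' @param centroid_a,centroid_b Marker centroids `c(x, y)` in pixels.
#' @param known_distance_mm Physical distance between the marker centres.
#' @return Pixel scale in px/mm.
#' @export
calibrate_scale <- function(centroid_a, centroid_b, known_distance_mm) {
  stopifnot(length(centroid_a) == 2L, length(centroid_b) == 2L,
            is.numeric(known_distance_mm), length(known_distance_mm) == 1L)
  if (!is.finite(known_distance_mm) || known_distance_mm <= 0)
    stop("'known_distance_mm' must be positive")
  d_px <- sqrt(sum((centroid_a - centroid_b)^2))
  if (d_px < .Machine$double.eps^0.5)
    stop("marker centroids coincide; cannot calibrate")
  d_px / known_distance_mm
}
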