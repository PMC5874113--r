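# Image pyramids for coarse-to-fine optical flow: 5-tap binomial low-pass
# followed by factor-2 decimation at each level.

# Separable [1 4 6 4 1]/16 smoothing with border replication.
.binomial5 <- function(img) {
  k <- c(1, 4, 6, 4, 1) / 16
  h <- nrow(img); w <- ncol(img)
  shift_rows <- function(m, s) {
    idx <- pmin(pmax(seq_len(h) + s, 1L), h)
    m[idx, , drop = FALSE]
  }
  shift_cols <- function(m, s) {
    idx <- pmin(pmax(seq_len(w) + s, 1L), w)
    m[, idx, drop = FALSE]
  }
  tmp <- k[1] * shift_rows(img, -2L) + k[2] * shift_rows(img, -1L) +
    k[3] * img + k[4] * shift_rows(img, 1L) + k[5] * shift_rows(img, 2L)
  k[1] * shift_cols(tmp, -2L) + k[2] * shift_cols(tmp, -1L) +
    k[3] * tmp + k[4] * shift_cols(tmp, 1L) + k[5] * shift_cols(tmp, 2L)
}

#' Build an image pyramid
#'
#' Level 1 is the original frame; each further level low-passes the previous
#' one with a 5-tap binomial kernel and keeps every second pixel (odd
#' indices), so level dimensions are `ceiling(previous / 2)`. The coarsest
#' level must remain at least 16 px in each dimension.
#'
#' @param frame Numeric matrix.
#' @param n_levels Number of levels (>= 1).
#' @return An object of class `image_pyramid`: list of matrices `levels`.
#' @export
build_pyramid <- function(frame, n_levels = 3) {
  .check_frame(frame)
  stopifnot(n_levels >= 1)
  top <- ceiling(dim(frame) / 2^(n_levels - 1))
  if (any(top < 16))
    stop(sprintf("frame %d x %d is too small for %d pyramid levels (coarsest level must be >= 16 px)",
                 ncol(frame), nrow(frame), n_levels))
  levels <- vector("list", n_levels)
  levels[[1L]] <- frame
  for (L in seq_len(n_levels - 1L)) {
    sm <- .binomial5(levels[[L]])
    levels[[L + 1L]] <- sm[seq(1L, nrow(sm), by = 2L),
                           seq(1L, ncol(sm), by = 2L), drop = FALSE]
  }
  structure(list(levels = levels, n_levels = n_levels),
            class = "image_pyramid")
}

# Map a level-1 (full resolution) coordinate to pyramid level L. Decimation
# keeps original pixels 1, 3, 5, ... so pixel x maps to (x - 1) / 2 + 1.
.to_level <- function(p, L) (p - 1) / 2^(L - 1) + 1
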