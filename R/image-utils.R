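# Low-level image primitives shared by detection and tracking. All frames
# are numeric matrices in [0, 1]; pixel (row i, col j) has its centre at
# image coordinates x = j, y = i.

.check_frame <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame) || length(frame) == 0L)
    stop("frame must be a non-empty numeric matrix")
  if (any(!is.finite(frame)))
    stop("frame contains non-finite values")
  invisible(frame)
}

# Central-difference gradients with border replication. Returns list(Ix, Iy).
.gradients <- function(frame) {
  h <- nrow(frame); w <- ncol(frame)
  left  <- frame[, c(1L, seq_len(w - 1L)), drop = FALSE]
  right <- frame[, c(seq_len(w)[-1L], w), drop = FALSE]
  up    <- frame[c(1L, seq_len(h - 1L)), , drop = FALSE]
  down  <- frame[c(seq_len(h)[-1L], h), , drop = FALSE]
  list(Ix = (right - left) / 2, Iy = (down - up) / 2)
}

# Bilinear interpolation of `img` at (x, y) vectors; coordinates are clamped
# to the valid interpolation domain [1, ncol] x [1, nrow].
.bilinear <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 1), w)
  y <- pmin(pmax(y, 1), h)
  x0 <- pmin(floor(x), w - 1L); y0 <- pmin(floor(y), h - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0 - 1) * h + y0          # linear index of (y0, x0)
  v00 <- img[i00];      v10 <- img[i00 + h]
  v01 <- img[i00 + 1];  v11 <- img[i00 + h + 1]
  (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11)
}

# Sliding box sum over a (2w+1)^2 window via an integral image. Border rows
# and columns (within w of the edge) use truncated windows.
.box_sum <- function(img, w) {
  h <- nrow(img); wd <- ncol(img)
  ii <- matrix(0, h + 1L, wd + 1L)
  cs <- apply(img, 2L, cumsum)                 # down columns
  if (h == 1L) cs <- matrix(cs, nrow = 1L)
  cs <- t(apply(cs, 1L, cumsum))               # then across rows
  if (wd == 1L) cs <- matrix(cs, ncol = 1L)
  ii[2:(h + 1L), 2:(wd + 1L)] <- cs
  y0 <- pmax(seq_len(h) - w, 1L); y1 <- pmin(seq_len(h) + w, h)
  x0 <- pmax(seq_len(wd) - w, 1L); x1 <- pmin(seq_len(wd) + w, wd)
  iy1 <- rep(y1 + 1L, times = wd); iy0 <- rep(y0, times = wd)
  ix1 <- rep(x1 + 1L, each = h);   ix0 <- rep(x0, each = h)
  s <- ii[cbind(iy1, ix1)] - ii[cbind(iy0, ix1)] -
       ii[cbind(iy1, ix0)] + ii[cbind(iy0, ix0)]
  matrix(s, nrow = h)
}

# True if a window of half-width w around sub-pixel point p = c(x, y) lies
# inside the frame with a 1-px bilinear margin.
.window_inside <- function(dim_hw, p, w) {
  p[1L] - w >= 1 && p[1L] + w <= dim_hw[2L] &&
    p[2L] - w >= 1 && p[2L] + w <= dim_hw[1L]
}
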