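# Low-level array helpers shared across modules. All image matrices are
# indexed [row, col]; frequencies are in cycles per pixel unless stated.

#' Two-dimensional FFT helpers
#'
#' Thin wrappers around [stats::fft()] for matrices; `ifft2` applies the
#' 1/N normalization so `ifft2(fft2(x))` recovers `x`.
#'
#' @param x complex or numeric matrix.
#' @return complex matrix of the same shape.
#' @keywords internal
fft2 <- function(x) stats::fft(x)

#' @rdname fft2
#' @keywords internal
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Signed FFT bin frequencies
#'
#' @param n number of samples.
#' @param d sample spacing.
#' @return length-`n` vector of frequencies in cycles per unit of `d`,
#'   ordered as the unshifted FFT output.
#' @keywords internal
fft_freq <- function(n, d = 1) {
  k <- c(seq(0L, ceiling(n / 2) - 1L), seq(-floor(n / 2), -1L))
  k / (n * d)
}

#' @keywords internal
fftshift2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  x[c((floor(n / 2) + 1):n, 1:floor(n / 2)),
    c((floor(m / 2) + 1):m, 1:floor(m / 2)), drop = FALSE]
}

#' Circular field-of-view mask
#'
#' The fiber core bounds the usable image region; pixels at radius greater
#' than `radius_px` from the grid centre are outside the field of view.
#'
#' @param shape integer pair (rows, cols).
#' @param radius_px mask radius in pixels; defaults to the inscribed circle.
#' @return logical matrix, `TRUE` inside the field of view.
#' @export
circular_mask <- function(shape, radius_px = NULL) {
  n <- shape[1]; m <- shape[2]
  if (is.null(radius_px)) radius_px <- min(n, m) / 2
  cy <- (n + 1) / 2; cx <- (m + 1) / 2
  r2 <- outer((seq_len(n) - cy)^2, (seq_len(m) - cx)^2, "+")
  r2 <= radius_px^2
}

#' Separable Gaussian blur with replicated edges
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; `sigma <= 0` returns `img`.
#' @return blurred matrix of the same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  blur_axis <- function(m) {
    # pad rows by replication, convolve columns of the padded matrix
    n <- nrow(m)
    idx <- c(rep(1L, half), seq_len(n), rep(n, half))
    p <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * p[j:(j + n - 1L), , drop = FALSE]
    }
    out
  }
  t(blur_axis(t(blur_axis(img))))
}

# median of 9 via Paeth's 19-op compare-exchange network (vectorized over
# pixels); op(a,b) leaves min at a, max at b; the median ends in slot 5
.median9 <- function(v) {
  ex <- function(a, b) {
    lo <- pmin(v[[a]], v[[b]]); hi <- pmax(v[[a]], v[[b]])
    v[[a]] <<- lo; v[[b]] <<- hi
  }
  ex(2, 3); ex(5, 6); ex(8, 9); ex(1, 2); ex(4, 5); ex(7, 8)
  ex(2, 3); ex(5, 6); ex(8, 9); ex(1, 4); ex(6, 9); ex(5, 8)
  ex(4, 7); ex(2, 5); ex(3, 6); ex(5, 8); ex(5, 3); ex(7, 5)
  ex(5, 3)
  v[[5]]
}

#' 3x3 median filter with replicated edges
#'
#' @param img numeric matrix, at least 3x3.
#' @return filtered matrix of the same shape.
#' @export
median_filter3 <- function(img) {
  n <- nrow(img); m <- ncol(img)
  stopifnot(n >= 3, m >= 3)
  ri <- function(d) pmin(pmax(seq_len(n) + d, 1L), n)
  ci <- function(d) pmin(pmax(seq_len(m) + d, 1L), m)
  v <- list()
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    v[[k]] <- img[ri(dr), ci(dc), drop = FALSE]
  }
  .median9(v)
}

#' Bilinear image resize
#'
#' @param img numeric matrix.
#' @param shape target (rows, cols).
#' @return resized matrix.
#' @export
resize_image <- function(img, shape) {
  n <- nrow(img); m <- ncol(img)
  no <- shape[1]; mo <- shape[2]
  # map output pixel centres onto input pixel-centre coordinates
  ry <- (seq_len(no) - 0.5) * n / no + 0.5 - 0.5
  rx <- (seq_len(mo) - 0.5) * m / mo + 0.5 - 0.5
  y0 <- pmin(pmax(floor(ry), 1), n); y1 <- pmin(y0 + 1, n)
  x0 <- pmin(pmax(floor(rx), 1), m); x1 <- pmin(x0 + 1, m)
  wy <- pmin(pmax(ry - y0, 0), 1); wx <- pmin(pmax(rx - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  c_ <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  Wy <- matrix(wy, no, mo); Wx <- matrix(wx, no, mo, byrow = TRUE)
  (1 - Wy) * ((1 - Wx) * a + Wx * b) + Wy * ((1 - Wx) * c_ + Wx * d)
}

#' Quantize gray values into equal-width bins
#'
#' Values inside `mask` are binned into `levels` equal-width bins spanning
#' the masked min..max range; a constant region maps to level 0.
#'
#' @param img numeric matrix.
#' @param levels number of gray bins.
#' @param mask logical matrix; defaults to all pixels.
#' @return integer matrix of levels in `0:(levels-1)`; `NA` outside mask.
#' @keywords internal
quantize_gray <- function(img, levels, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  v <- img[mask]
  lo <- min(v); hi <- max(v)
  q <- matrix(NA_integer_, nrow(img), ncol(img))
  if (hi <= lo) {
    q[mask] <- 0L
    return(q)
  }
  b <- as.integer(pmin(floor((img[mask] - lo) / (hi - lo) * levels), levels - 1L))
  q[mask] <- b
  q
}

#' Map an image to pseudocolor for display
#'
#' Pure display mapping: stored pixel values are never altered. Returns an
#' rows x cols x 3 array of RGB values in `[0, 1]` using an
#' inferno-like ramp.
#'
#' @param img numeric matrix.
#' @return numeric array `c(dim(img), 3)`.
#' @export
pseudocolor <- function(img) {
  rng <- range(img)
  x <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  ramp <- grDevices::colorRamp(c("#000004", "#56106e", "#bb3754",
                                 "#f98c0a", "#fcffa4"))
  rgb <- ramp(as.vector(x)) / 255
  array(rgb, dim = c(dim(img), 3))
}
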