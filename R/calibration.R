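# Off-axis interferometric calibration of the transmission matrix.
#
# Each probe mode is sent through the fiber; the camera records the
# intensity interferogram of the output field with a tilted plane-wave
# reference, and the complex field is recovered from the off-axis sideband
# by Fourier filtering. The camera oversamples the facet field (factor
# `oversample`, default 5) so the sideband, its conjugate and the
# autocorrelation term are strictly disjoint in the Fourier plane --
# including their circular wrap-arounds -- and noiseless recovery is exact
# up to one global phase.

# embed an n x m field on an (M*n) x (M*m) camera grid (Fourier zero-pad)
.upsample_field <- function(e, M) {
  n <- nrow(e); m <- ncol(e)
  f <- fft2(e)
  Nf <- M * n; Mf <- M * m
  ff <- matrix(0i, Nf, Mf)
  ob_r <- c(seq(0L, n %/% 2 - 1L), seq(-(n %/% 2), -1L))
  ob_c <- c(seq(0L, m %/% 2 - 1L), seq(-(m %/% 2), -1L))
  ff[(ob_r %% Nf) + 1L, (ob_c %% Mf) + 1L] <- f
  ifft2(ff) * M^2
}

#' Simulate off-axis interferometric calibration of a transmission matrix
#'
#' @param tm_true ground-truth `transmission_matrix` (square grid).
#' @param basis probe basis: `"onehot"` (identity probes) or an invertible
#'   `n_modes x n_modes` complex matrix whose columns are probe vectors.
#' @param noise_sd additive Gaussian camera noise, as a fraction of the
#'   mean hologram intensity (0 = noiseless).
#' @param ref_amplitude plane-wave reference amplitude; must be positive.
#' @param oversample camera oversampling factor relative to the field grid
#'   (integer >= 5 so sideband, conjugate and autocorrelation separate
#'   without wrap-around).
#' @param tilt_frac reference tilt in cycles per camera pixel along both
#'   axes; default `3/8`.
#' @param seed seed for the noise draws.
#' @return a `tm_estimate` object: `entries` (complex matrix shaped like
#'   the truth, global phase fixed so the first entry is real-positive) and
#'   `fidelity` (complex correlation with the truth, in `[0, 1]`).
#' @export
simulate_offaxis_calibration <- function(tm_true, basis = "onehot",
                                         noise_sd = 0, ref_amplitude = 1,
                                         oversample = 5L, tilt_frac = 3 / 8,
                                         seed = 1L) {
  stopifnot(inherits(tm_true, "transmission_matrix"))
  if (ref_amplitude <= 0) {
    stop("demodulation error: zero (or negative) reference amplitude")
  }
  gs <- tm_true$config$grid_shape
  n <- gs[1]; m <- gs[2]
  if (n %% 2 != 0 || m %% 2 != 0) stop("grid dimensions must be even")
  M <- as.integer(oversample)
  if (M < 5) stop("oversample must be at least 5")
  Nf <- M * n; Mf <- M * m
  cb_r <- round(tilt_frac * Nf); cb_c <- round(tilt_frac * Mf)
  # sideband-separation bound: the demodulation window (half-width n/2
  # bins) must clear the autocorrelation term (half-width n-1 bins), and
  # the conjugate sideband must not wrap past Nyquist into the window
  if (cb_r < 1.5 * n - 1 || cb_c < 1.5 * m - 1 ||
      cb_r > Nf / 2 - n / 2 - 1 || cb_c > Mf / 2 - m / 2 - 1) {
    stop("demodulation error: reference tilt below sideband-separation bound")
  }
  set.seed(as.integer(seed))
  xr <- matrix(seq_len(Nf) - 1, Nf, Mf)
  xc <- matrix(seq_len(Mf) - 1, Nf, Mf, byrow = TRUE)
  ref <- ref_amplitude * exp(2i * pi * (cb_r * xr / Nf + cb_c * xc / Mf))

  n_modes <- tm_true$n_modes
  if (is.character(basis) && identical(basis, "onehot")) {
    bmat <- NULL
  } else {
    bmat <- as.matrix(basis)
    if (nrow(bmat) != n_modes || ncol(bmat) != n_modes) {
      stop("basis matrix must be n_modes x n_modes")
    }
  }
  probe_field <- function(j) {
    a <- if (is.null(bmat)) {
      tm_true$entries[, j]
    } else {
      tm_true$entries %*% bmat[, j]
    }
    matrix(a, n, m)
  }

  ob_r <- c(seq(0L, n %/% 2 - 1L), seq(-(n %/% 2), -1L))
  ob_c <- c(seq(0L, m %/% 2 - 1L), seq(-(m %/% 2), -1L))
  ridx <- ((ob_r - cb_r) %% Nf) + 1L   # sideband of E*conj(R) sits at -carrier
  cidx <- ((ob_c - cb_c) %% Mf) + 1L
  est <- matrix(0i, n * m, n_modes)
  for (j in seq_len(n_modes)) {
    ef <- .upsample_field(probe_field(j), M)
    holo <- Mod(ef + ref)^2
    if (noise_sd > 0) {
      holo <- holo + noise_sd * mean(holo) * stats::rnorm(length(holo))
    }
    g <- fft2(holo)
    fhat <- g[ridx, cidx, drop = FALSE] / (ref_amplitude * M^2)
    est[, j] <- as.vector(ifft2(fhat))
  }
  if (!is.null(bmat)) est <- est %*% solve(bmat)
  # resolve the global phase: first entry real-positive
  if (Mod(est[1, 1]) > 0) est <- est * exp(-1i * Arg(est[1, 1]))
  fid <- tm_fidelity(est, tm_true$entries)
  structure(list(entries = est, config = tm_true$config,
                 n_modes = n_modes, fidelity = fid,
                 noise_sd = noise_sd),
            class = c("tm_estimate", "transmission_matrix"))
}

#' Complex correlation fidelity between two matrices
#'
#' `|<A, B>| / (||A|| * ||B||)`; equals 1 iff the matrices agree up to one
#' global complex scale.
#'
#' @param a,b complex matrices of equal shape.
#' @return fidelity in `[0, 1]`.
#' @export
tm_fidelity <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  Mod(sum(Conj(a) * b)) / sqrt(sum(Mod(a)^2) * sum(Mod(b)^2))
}
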