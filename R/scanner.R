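# Point-scan image formation through the fiber.
#
# The probe focus is raster-scanned over a square lattice at the output
# pixel pitch, inscribed in the circular core aperture; the detected signal
# at each position becomes one pixel. With a single-bucket (non-descanned)
# detector the effective PSF is the illumination focus intensity, so
# "ideal_psf" mode convolves the phantom with the diffraction-limited Airy
# intensity and "speckle" mode uses the actual phase-conjugate focus of a
# transmission matrix, background speckle included.

#' Construct a scan image
#'
#' @param pixels non-negative numeric matrix.
#' @param pixel_size_um pixel pitch in micrometers.
#' @param z axial depth of the focal plane in micrometers.
#' @param mask logical field-of-view mask; pixels outside are zeroed.
#' @return a `scan_image` object.
#' @export
scan_image <- function(pixels, pixel_size_um, z = 0, mask = NULL) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)))
  if (is.null(mask)) mask <- circular_mask(dim(pixels))
  pixels[!mask] <- 0
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 z = z, fov_mask = mask),
            class = "scan_image")
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("<scan_image> %dx%d px @ %.3g um, z=%.4g um\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$z))
  invisible(x)
}

#' Diffraction-limited Airy intensity PSF
#'
#' Radially symmetric `(2 J1(v)/v)^2` with first zero at the Rayleigh
#' radius `0.61 * lambda / NA`.
#'
#' @param config an [optical_config()].
#' @param shape kernel shape in pixels (odd sizes keep the peak centred).
#' @param pixel_size_um sampling; defaults to `config$pixel_size_um`.
#' @return matrix summing to 1.
#' @export
airy_psf <- function(config, shape = NULL, pixel_size_um = NULL) {
  if (is.null(pixel_size_um)) pixel_size_um <- config$pixel_size_um
  r0 <- 0.61 * config$wavelength_um / config$na
  if (is.null(shape)) {
    h <- max(5L, 2L * ceiling(3 * r0 / pixel_size_um) + 1L)
    shape <- c(h, h)
  }
  cy <- (shape[1] + 1) / 2; cx <- (shape[2] + 1) / 2
  r <- sqrt(outer(((seq_len(shape[1]) - cy) * pixel_size_um)^2,
                  ((seq_len(shape[2]) - cx) * pixel_size_um)^2, "+"))
  v <- 3.8317060 * r / r0
  psf <- matrix(1, shape[1], shape[2])
  nz <- v > 1e-9
  psf[nz] <- (2 * besselJ(v[nz], 1) / v[nz])^2
  psf / sum(psf)
}

# linear FFT convolution with replicated edges, 'same' output size
# (replication avoids vignetting: the tissue extends beyond the frame)
.fft_conv_same <- function(img, ker) {
  n <- nrow(img); m <- ncol(img)
  kn <- nrow(ker); km <- ncol(ker)
  hr <- (kn - 1L) %/% 2; hc <- (km - 1L) %/% 2
  ri <- pmin(pmax(seq(1 - hr, n + hr), 1L), n)
  ci <- pmin(pmax(seq(1 - hc, m + hc), 1L), m)
  ext <- img[ri, ci, drop = FALSE]
  pn <- nrow(ext) + kn - 1L; pm <- ncol(ext) + km - 1L
  a <- matrix(0, pn, pm); a[seq_len(nrow(ext)), seq_len(ncol(ext))] <- ext
  b <- matrix(0, pn, pm); b[1:kn, 1:km] <- ker
  full <- Re(ifft2(fft2(a) * fft2(b)))
  full[(2 * hr + 1):(2 * hr + n), (2 * hc + 1):(2 * hc + m), drop = FALSE]
}

# central crop (or zero-pad) of a matrix to the requested shape
.center_crop <- function(img, shape) {
  n <- nrow(img); m <- ncol(img)
  if (n == shape[1] && m == shape[2]) return(img)
  out <- matrix(0, shape[1], shape[2])
  r0 <- max(0L, (n - shape[1]) %/% 2)
  c0 <- max(0L, (m - shape[2]) %/% 2)
  ro <- max(0L, (shape[1] - n) %/% 2)
  co <- max(0L, (shape[2] - m) %/% 2)
  nr <- min(n, shape[1]); nc <- min(m, shape[2])
  out[(ro + 1):(ro + nr), (co + 1):(co + nc)] <-
    img[(r0 + 1):(r0 + nr), (c0 + 1):(c0 + nc)]
  out
}

#' Acquire a point-scan image of a phantom
#'
#' @param tm a `transmission_matrix` (required for `"speckle"` mode; in
#'   `"ideal_psf"` mode only its `config` is used, and a bare
#'   [optical_config()] is accepted instead).
#' @param phantom a [phantom()] whose pixel size matches the configuration.
#' @param mode `"ideal_psf"` (Airy-intensity convolution, fast) or
#'   `"speckle"` (explicit phase-conjugate focus per scan position,
#'   speckle background included).
#' @param noise_peak expected photon count at the brightest pixel for
#'   Poisson noise; `NULL` disables noise.
#' @param seed seed for the noise draws.
#' @return a `scan_image` on the configured grid, circularly cropped to
#'   the core field of view.
#' @export
acquire_scan <- function(tm, phantom, mode = c("ideal_psf", "speckle"),
                         noise_peak = NULL, seed = 1L) {
  mode <- match.arg(mode)
  config <- if (inherits(tm, "transmission_matrix")) tm$config else tm
  stopifnot(inherits(config, "optical_config"), inherits(phantom, "phantom"))
  if (abs(phantom$pixel_size_um - config$pixel_size_um) >
      1e-6 * config$pixel_size_um) {
    stop("phantom pixel size must match the optical configuration")
  }
  dens <- phantom_slice(phantom)
  gs <- config$grid_shape
  mask <- circular_mask(gs, fov_radius_px(config))
  if (mode == "ideal_psf") {
    img <- .fft_conv_same(dens, airy_psf(config))
    img <- .center_crop(img, gs)
  } else {
    if (!inherits(tm, "transmission_matrix")) {
      stop("speckle mode requires a transmission_matrix")
    }
    cwin <- .center_crop(dens, gs)
    cvec <- as.vector(cwin)
    img <- matrix(0, gs[1], gs[2])
    for (p in which(as.vector(mask))) {
      a <- exp(-1i * Arg(tm$entries[p, ])) / sqrt(tm$n_modes)
      ip <- Mod(tm$entries %*% a)^2
      img[p] <- sum(ip * cvec)
    }
  }
  img[img < 0] <- 0
  if (!is.null(noise_peak)) {
    set.seed(as.integer(seed))
    pk <- max(img)
    if (pk > 0) {
      img <- matrix(stats::rpois(length(img), img / pk * noise_peak),
                    gs[1], gs[2]) * pk / noise_peak
    }
  }
  scan_image(img, config$pixel_size_um, z = phantom_z(phantom), mask = mask)
}

#' Reconstruct a scan image from raw detector signals
#'
#' Reshapes the signal list onto the scan grid (column-major), optionally
#' denoises, and crops to the circular field of view. Pseudocolor display
#' mapping is available separately via [pseudocolor()] and never alters
#' stored values.
#'
#' @param signals numeric vector, one signal per grid node.
#' @param grid_shape integer pair (rows, cols) of the scan lattice.
#' @param pixel_size_um pixel pitch in micrometers.
#' @param denoise `"median"` (3x3), `"gaussian"` (sigma 0.8) or `"none"`.
#' @param mask optional logical mask; default inscribed circle.
#' @param z axial depth tag.
#' @return a `scan_image`.
#' @export
reconstruct <- function(signals, grid_shape, pixel_size_um = 1,
                        denoise = c("none", "median", "gaussian"),
                        mask = NULL, z = 0) {
  denoise <- match.arg(denoise)
  if (length(signals) != prod(grid_shape)) {
    stop(sprintf("signal length %d does not match grid %dx%d",
                 length(signals), grid_shape[1], grid_shape[2]))
  }
  img <- matrix(signals, grid_shape[1], grid_shape[2])
  img <- switch(denoise,
                none = img,
                median = median_filter3(img),
                gaussian = gaussian_blur(img, 0.8))
  scan_image(img, pixel_size_um, z = z, mask = mask)
}
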