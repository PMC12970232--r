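# Synthetic tissue phantoms. These emulate the *statistical* structure of
# ICG-enhanced puncture images, not anatomy: normal lung is a quasi-regular
# lattice of dark round-to-oval alveolar voids bordered by bright
# perfused septa; tumor tissue is disordered, heterogeneous and rich in
# fine-scale (high-frequency) content, with a higher proportion of bright
# pixels. Optical test targets (line pairs, two points) support the
# resolution checks.

#' Construct a phantom
#'
#' @param density non-negative 2-D matrix or 3-D array of fluorophore
#'   density (arbitrary units).
#' @param pixel_size_um physical pixel size in micrometers.
#' @param label one of `"normal"`, `"tumor"`, `"target"`.
#' @param params generator parameters (free-form list, for provenance).
#' @param seed integer seed the phantom was generated from.
#' @param z_um axial slice positions (micrometers) for 3-D phantoms;
#'   strictly increasing.
#' @return a `phantom` object.
#' @export
phantom <- function(density, pixel_size_um, label = "target",
                    params = list(), seed = NA_integer_, z_um = NULL) {
  label <- match.arg(label, c("normal", "tumor", "target"))
  stopifnot(all(is.finite(density)), all(density >= 0))
  if (!is.null(z_um)) {
    stopifnot(length(dim(density)) == 3,
              length(z_um) == dim(density)[3])
    if (any(diff(z_um) <= 0)) stop("z_um must be strictly increasing")
  }
  structure(list(density = density, pixel_size_um = pixel_size_um,
                 label = label, params = params, seed = seed, z_um = z_um),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$density)
  cat(sprintf("<phantom:%s> %s px @ %.3g um%s\n", x$label,
              paste(d, collapse = "x"), x$pixel_size_um,
              if (is.null(x$z_um)) "" else
                sprintf(", z %g..%g um", min(x$z_um), max(x$z_um))))
  invisible(x)
}

#' @keywords internal
phantom_slice <- function(p, k = 1L) {
  if (is.null(p$z_um)) p$density else p$density[, , k]
}

#' @keywords internal
phantom_z <- function(p, k = 1L) if (is.null(p$z_um)) 0 else p$z_um[k]

# periodic smooth Gaussian random field, zero mean, unit variance;
# degenerates to zeros when the correlation scale far exceeds the frame
.smooth_field <- function(shape, sigma_px) {
  n <- shape[1]; m <- shape[2]
  w <- matrix(stats::rnorm(n * m), n, m)
  fy <- fft_freq(n); fx <- fft_freq(m)
  h <- exp(-2 * pi^2 * sigma_px^2 * outer(fy^2, fx^2, "+"))
  h[1, 1] <- 0
  f <- Re(ifft2(fft2(w) * h))
  s <- stats::sd(f)
  if (s < 1e-9) return(matrix(0, n, m))
  f / s
}

# spectrally shaped 1/f^(beta/2) amplitude noise, unit variance
.shaped_noise <- function(shape, beta, f0 = 0.01) {
  n <- shape[1]; m <- shape[2]
  w <- matrix(stats::rnorm(n * m), n, m)
  fy <- fft_freq(n); fx <- fft_freq(m)
  fr <- sqrt(outer(fy^2, fx^2, "+"))
  amp <- (fr + f0)^(-beta / 2)
  amp[1, 1] <- 0
  f <- Re(ifft2(fft2(w) * amp))
  f / stats::sd(f)
}

#' Alveolar (normal lung) texture phantom
#'
#' Jittered hexagonal lattice of dark elliptical voids (gas-filled
#' alveoli) bordered by bright rims (ICG-perfused interalveolar septa) on
#' a moderate fluorescent background.
#'
#' @param shape image shape in pixels.
#' @param pixel_size_um pixel size; default 0.4 um (256 px ~ 102 um field,
#'   a hundred-micrometer-scale field of view).
#' @param mean_radius_um mean void radius; default 8 um.
#' @param radius_cv coefficient of variation of void radii, in `[0, 0.5)`.
#' @param rim_brightness peak septal brightness (background is 0.35).
#' @param jitter lattice jitter in `[0, 1]` (fraction of the free gap).
#' @param aspect_max maximum ellipse aspect ratio (<= 1.3: round-to-oval).
#' @param spacing_um hexagonal lattice pitch; the default adapts to the
#'   radius spread so voids cannot overlap. An explicit pitch smaller than
#'   the largest drawn void raises an overlap error.
#' @param seed integer seed.
#' @return a `phantom` with label `"normal"`.
#' @export
alveolar_phantom <- function(shape = c(256, 256), pixel_size_um = 0.4,
                             mean_radius_um = 8, radius_cv = 0.15,
                             rim_brightness = 1, jitter = 0.3,
                             aspect_max = 1.2, spacing_um = NULL,
                             seed = 1L) {
  stopifnot(radius_cv >= 0, radius_cv < 0.5, jitter >= 0, jitter <= 1,
            aspect_max >= 1, aspect_max <= 1.3)
  set.seed(as.integer(seed))
  n <- shape[1]; m <- shape[2]
  r_px <- mean_radius_um / pixel_size_um
  # hex lattice pitch; radius draws are truncated at 2.5 sd so the default
  # pitch guarantees non-overlapping voids
  spacing <- if (is.null(spacing_um)) {
    2.1 * r_px * (1 + 2.5 * radius_cv)
  } else {
    spacing_um / pixel_size_um
  }
  rim_w <- max(1.2 / pixel_size_um, 1.5)

  # hexagonal lattice covering the frame with one ring of margin
  rows <- seq(-spacing, n + spacing, by = spacing * sqrt(3) / 2)
  centers <- NULL
  for (i in seq_along(rows)) {
    off <- if (i %% 2 == 0) spacing / 2 else 0
    cols <- seq(-spacing + off, m + spacing, by = spacing)
    centers <- rbind(centers, cbind(rows[i], cols))
  }
  k <- nrow(centers)
  rr <- r_px * (1 + radius_cv * pmax(pmin(stats::rnorm(k), 2.5), -2.5))
  if (any(rr > spacing / 2)) {
    stop("overlap error: drawn void radius exceeds half the lattice spacing")
  }
  gap <- pmax(spacing / 2 - rr, 0)
  centers <- centers + jitter * cbind(stats::runif(k, -1, 1) * gap,
                                      stats::runif(k, -1, 1) * gap)
  asp <- stats::runif(k, 1, aspect_max)
  th <- stats::runif(k, 0, pi)
  rimb <- rim_brightness * (1 + 0.1 * stats::rnorm(k))

  base <- 0.35
  dens <- matrix(base, n, m)
  rho_min <- matrix(Inf, n, m)          # normalized elliptical distance
  rim_val <- matrix(0, n, m)
  for (j in seq_len(k)) {
    a <- rr[j] * sqrt(asp[j]); b <- rr[j] / sqrt(asp[j])
    ext <- ceiling(a + rim_w + 2)
    r0 <- max(1, floor(centers[j, 1] - ext)); r1 <- min(n, ceiling(centers[j, 1] + ext))
    c0 <- max(1, floor(centers[j, 2] - ext)); c1 <- min(m, ceiling(centers[j, 2] + ext))
    if (r0 > r1 || c0 > c1) next
    yy <- (r0:r1) - centers[j, 1]; xx <- (c0:c1) - centers[j, 2]
    u <- outer(yy * cos(th[j]), xx * sin(th[j]), "+")
    v <- outer(-yy * sin(th[j]), xx * cos(th[j]), "+")
    rho <- sqrt((u / a)^2 + (v / b)^2)
    # rescale so rho = 1 at the void edge and the rim spans rim_w pixels
    reff <- sqrt(a * b)
    band <- (rho - 1) * reff / rim_w    # 0 at edge, 1 at outer rim edge
    blk <- rho_min[r0:r1, c0:c1]
    sel <- rho < blk
    blk[sel] <- rho[sel]
    rho_min[r0:r1, c0:c1] <- blk
    rimblk <- rim_val[r0:r1, c0:c1]
    inrim <- band >= 0 & band <= 1
    rimblk[inrim] <- pmax(rimblk[inrim],
                          rimb[j] * sin(pi * pmin(pmax(band[inrim], 0), 1)))
    rim_val[r0:r1, c0:c1] <- rimblk
  }
  dens[rho_min < 1] <- 0.06             # dark gas-filled voids
  rim <- rim_val > dens & rho_min >= 1
  dens[rim] <- rim_val[rim]
  # gentle illumination field; fine detector noise is smoothed by the
  # same optical blur so the normal spectrum stays compact
  dens <- dens * (1 + 0.05 * .smooth_field(shape, 40))
  dens <- dens + 0.03 * stats::rnorm(n * m)
  dens <- gaussian_blur(dens, 1)
  dens[dens < 0] <- 0
  phantom(dens, pixel_size_um, label = "normal", seed = seed,
          params = list(mean_radius_um = mean_radius_um,
                        radius_cv = radius_cv,
                        rim_brightness = rim_brightness, jitter = jitter,
                        aspect_max = aspect_max))
}

#' Tumor texture phantom
#'
#' Correlated random blob field standing in for disorganized tumor tissue:
#' spectrally shaped noise whose high-frequency weight grows with
#' `disorder`, multiplied by a smooth patchiness field
#' (`heterogeneity`), blended with an alveolar remnant scaled by
#' `1 - disorder`, and brighter on average than normal tissue (elevated
#' ICG accumulation). At `disorder = 0` the alveolar component is returned
#' unchanged.
#'
#' @inheritParams alveolar_phantom
#' @param disorder structural disorder in `[0, 1]`.
#' @param blob_scale_um correlation scale of the blob field.
#' @param heterogeneity multiplicative intensity patchiness in `[0, 1]`.
#' @return a `phantom` with label `"tumor"`.
#' @export
tumor_phantom <- function(shape = c(256, 256), pixel_size_um = 0.4,
                          disorder = 1, blob_scale_um = 6,
                          heterogeneity = 0.6, mean_radius_um = 8,
                          seed = 1L) {
  stopifnot(disorder >= 0, disorder <= 1, heterogeneity >= 0,
            heterogeneity <= 1)
  alv <- alveolar_phantom(shape, pixel_size_um,
                          mean_radius_um = mean_radius_um, seed = seed)
  if (disorder == 0) {
    alv$label <- "tumor"
    alv$params <- list(disorder = 0, blob_scale_um = blob_scale_um,
                       heterogeneity = heterogeneity)
    return(alv)
  }
  set.seed(as.integer(seed) + 7L)
  beta <- 2.5 - 1.5 * disorder          # flatter spectrum when disordered
  f0 <- pixel_size_um / blob_scale_um
  blobs <- .shaped_noise(shape, beta, f0)
  fine <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  # sharp-edged bright clumps emulate the stacked, disorganized cell
  # masses; fine grain supplies the elevated high-frequency content
  clump <- 1 / (1 + exp(-(blobs - 0.5) / 0.12))
  tum <- 0.75 + 0.22 * blobs + 0.20 * disorder * fine +
    0.35 * disorder * clump
  # multiplicative patchiness concentrates spectral energy at the patch
  # scale (heterogeneous ICG accumulation)
  patch <- exp(heterogeneity * .smooth_field(shape, 35))
  tum <- tum * patch / mean(patch)
  dens <- (1 - disorder) * alv$density + disorder * tum
  dens[dens < 0] <- 0
  phantom(dens, pixel_size_um, label = "tumor", seed = seed,
          params = list(disorder = disorder,
                        blob_scale_um = blob_scale_um,
                        heterogeneity = heterogeneity))
}

#' Line-pair resolution target
#'
#' Binary bar pattern: `lp_per_mm` line pairs per millimetre gives a bar
#' width of `1000 / (2 * lp_per_mm)` micrometers; the duty cycle along the
#' modulation axis is 1/2 (exact when the period is an even number of
#' pixels).
#'
#' @param lp_per_mm line pairs per millimetre.
#' @param pixel_size_um pixel size in micrometers.
#' @param shape image shape.
#' @return a `phantom` with label `"target"`.
#' @export
linepair_target <- function(lp_per_mm, pixel_size_um, shape = c(128, 128)) {
  period_um <- 1000 / lp_per_mm
  period_px <- period_um / pixel_size_um
  if (period_px < 2) {
    stop("sampling error: bar period below 2 pixels (sub-Nyquist)")
  }
  x <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  dens <- ((x %% period_px) < period_px / 2) * 1
  phantom(dens, pixel_size_um, label = "target",
          params = list(lp_per_mm = lp_per_mm,
                        bar_width_um = period_um / 2))
}

#' Two-point resolution target
#'
#' Two unit impulses separated by `separation_um` along the row axis,
#' centred in the frame. Impulse positions use nearest-pixel rounding of
#' `centre +/- separation/2`; a zero separation stacks both impulses on
#' one pixel (weight 2). Total integrated density is always 2.
#'
#' @param separation_um centre-to-centre separation in micrometers.
#' @param pixel_size_um pixel size.
#' @param shape image shape.
#' @return a `phantom` with label `"target"`.
#' @export
two_point_target <- function(separation_um, pixel_size_um,
                             shape = c(65, 65)) {
  if (separation_um > 0 && separation_um < 2 * pixel_size_um) {
    stop("separation below 2 pixels is not representable")
  }
  dens <- matrix(0, shape[1], shape[2])
  cy <- round((shape[1] + 1) / 2)
  cx <- (shape[2] + 1) / 2
  c1 <- round(cx - separation_um / 2 / pixel_size_um)
  c2 <- round(cx + separation_um / 2 / pixel_size_um)
  dens[cy, c1] <- dens[cy, c1] + 1
  dens[cy, c2] <- dens[cy, c2] + 1
  phantom(dens, pixel_size_um, label = "target",
          params = list(separation_um = separation_um))
}

#' Volume with texture confined to one plane (autofocus test object)
#'
#' @param z_texture depth of the textured slice (micrometers).
#' @param z_um slice positions.
#' @param shape,pixel_size_um,seed as in [alveolar_phantom()].
#' @return a 3-D `phantom`.
#' @export
focus_test_volume <- function(z_texture, z_um = seq(0, 60, by = 20),
                              shape = c(64, 64), pixel_size_um = 0.4,
                              seed = 1L) {
  set.seed(as.integer(seed))
  vol <- array(0.3, dim = c(shape, length(z_um)))
  k <- which.min(abs(z_um - z_texture))
  tex <- 0.3 + 0.25 * .shaped_noise(shape, beta = 1, f0 = 0.05)
  tex[tex < 0] <- 0
  vol[, , k] <- tex
  phantom(vol, pixel_size_um, label = "target", seed = seed,
          params = list(z_texture = z_um[k]), z_um = z_um)
}

#' Volume whose texture coarsens with depth (puncture test object)
#'
#' The slice at depth z mixes a coarse blob background with a fine-grain
#' component whose amplitude falls linearly with depth (structures
#' coarsen and fine-scale content fades as the needle advances), so the
#' GLCM contrast of an autofocused depth series decreases monotonically
#' by construction.
#'
#' @param z_um slice positions (micrometers); keep slices >= 40 um apart
#'   so out-of-focus planes are strongly defocused.
#' @param fine_amp_range fine-grain amplitude at the first and last slice.
#' @param blob_scale_range_um coarse correlation scale at the first and
#'   last slice.
#' @param shape,pixel_size_um,seed as in [alveolar_phantom()].
#' @return a 3-D `phantom`.
#' @export
puncture_volume <- function(z_um = seq(0, 80, by = 40),
                            fine_amp_range = c(0.25, 0.04),
                            blob_scale_range_um = c(4, 12),
                            shape = c(64, 64), pixel_size_um = 0.4,
                            seed = 1L) {
  set.seed(as.integer(seed))
  nz <- length(z_um)
  scales <- seq(blob_scale_range_um[1], blob_scale_range_um[2],
                length.out = nz)
  amps <- seq(fine_amp_range[1], fine_amp_range[2], length.out = nz)
  vol <- array(0, dim = c(shape, nz))
  for (k in seq_len(nz)) {
    sl <- 0.5 + 0.15 * .smooth_field(shape, scales[k] / pixel_size_um) +
      amps[k] * .smooth_field(shape, 1.5)
    sl[sl < 0] <- 0
    vol[, , k] <- sl
  }
  phantom(vol, pixel_size_um, label = "target", seed = seed,
          params = list(fine_amp_range = fine_amp_range,
                        blob_scale_range_um = blob_scale_range_um),
          z_um = z_um)
}

#' Balanced labeled phantom cohort
#'
#' Generates `n_per_class` normal and tumor phantoms each (or an
#' unbalanced pair when `n_per_class` has length 2, e.g. `c(194, 193)`
#' for a 387-image set), with generator parameters drawn per image from
#' realistic ranges. `"direct"` mode renders phantom densities as images;
#' `"through_fiber"` acquires each through the scanner
#' ([acquire_scan()], ideal-PSF mode with Poisson noise).
#'
#' @param n_per_class scalar or `c(n_normal, n_tumor)`; each >= 2.
#' @param image_size image shape in pixels.
#' @param pixel_size_um pixel size.
#' @param seed master seed; per-image seeds derive from it.
#' @param mode `"direct"` or `"through_fiber"`.
#' @param config optical configuration for `"through_fiber"`; defaults to
#'   the NA 0.37 test probe sampled at `pixel_size_um` with a core
#'   covering the frame.
#' @param noise_peak Poisson peak count for `"through_fiber"` (default
#'   500).
#' @return a `phantom_cohort`: list with `images` (list of matrices),
#'   `labels`, and `manifest` (data.frame `filename,label,seed`).
#' @export
cohort <- function(n_per_class, image_size = c(256, 256),
                   pixel_size_um = 0.4, seed = 1L,
                   mode = c("direct", "through_fiber"), config = NULL,
                   noise_peak = 500) {
  mode <- match.arg(mode)
  if (length(n_per_class) == 1) n_per_class <- rep(n_per_class, 2)
  stopifnot(all(n_per_class >= 2))
  if (mode == "through_fiber" && is.null(config)) {
    config <- optical_config(0.785, 0.37,
                             core_diameter_um = max(image_size) * pixel_size_um,
                             pixel_size_um = pixel_size_um,
                             grid_shape = image_size)
  }
  set.seed(as.integer(seed))
  total <- sum(n_per_class)
  seeds <- sample.int(.Machine$integer.max - 10L, total)
  labels <- rep(c("normal", "tumor"), n_per_class)
  images <- vector("list", total)
  for (i in seq_len(total)) {
    set.seed(seeds[i])
    ph <- if (labels[i] == "normal") {
      alveolar_phantom(image_size, pixel_size_um,
                       mean_radius_um = stats::runif(1, 7, 9.5),
                       radius_cv = stats::runif(1, 0.1, 0.2),
                       rim_brightness = stats::runif(1, 0.85, 1.15),
                       jitter = stats::runif(1, 0.2, 0.45),
                       seed = seeds[i])
    } else {
      tumor_phantom(image_size, pixel_size_um,
                    disorder = stats::runif(1, 0.8, 1),
                    blob_scale_um = stats::runif(1, 5, 8),
                    heterogeneity = stats::runif(1, 0.4, 0.7),
                    seed = seeds[i])
    }
    images[[i]] <- if (mode == "direct") {
      ph$density
    } else {
      acquire_scan(config, ph, mode = "ideal_psf",
                   noise_peak = noise_peak, seed = seeds[i])$pixels
    }
  }
  manifest <- data.frame(
    filename = sprintf("img_%04d.pgm", seq_len(total)),
    label = labels, seed = seeds, stringsAsFactors = FALSE)
  structure(list(images = images, labels = labels, manifest = manifest,
                 pixel_size_um = pixel_size_um, mode = mode, seed = seed),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d images (%s), mode %s\n",
              length(x$images),
              paste(table(x$labels), collapse = " + "), x$mode))
  invisible(x)
}
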