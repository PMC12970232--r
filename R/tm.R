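# Transmission-matrix model of the multimode fiber.
#
# The fiber is idealized as a fully scrambling linear map: entries are
# i.i.d. circular-complex Gaussian, then each column (input mode) is
# normalized to unit mean square over output pixels so every mode carries
# the same energy. A 3-D matrix is the facet matrix composed with
# angular-spectrum propagators at the listed axial planes.

#' Generate a random multimode-fiber transmission matrix
#'
#' @param config an [optical_config()]; output pixels are
#'   `prod(config$grid_shape)`.
#' @param n_modes number of input modes (columns); see
#'   [mode_count_estimate()] for a physically motivated choice.
#' @param seed integer seed; the matrix is a pure function of
#'   `(config, n_modes, seed)`.
#' @param z_planes optional strictly increasing axial offsets (micrometers)
#'   for a 3-D matrix; plane matrices are derived on demand by
#'   [tm_at_plane()].
#' @return a `transmission_matrix` object with fields `entries`
#'   (complex, n_pixels x n_modes), `config`, `seed`, `z_planes`.
#' @export
generate_tm <- function(config, n_modes, seed = 1L, z_planes = NULL) {
  stopifnot(inherits(config, "optical_config"))
  if (length(n_modes) != 1 || n_modes < 1) {
    stop("n_modes must be a positive integer")
  }
  n_modes <- as.integer(n_modes)
  if (!is.null(z_planes)) {
    z_planes <- as.numeric(z_planes)
    if (any(diff(z_planes) <= 0)) stop("z_planes must be strictly increasing")
  }
  n_pix <- prod(config$grid_shape)
  set.seed(as.integer(seed))
  e <- matrix(complex(real = stats::rnorm(n_pix * n_modes),
                      imaginary = stats::rnorm(n_pix * n_modes)) / sqrt(2),
              n_pix, n_modes)
  # unit second moment per column: mean |t|^2 = 1
  cn <- sqrt(colMeans(Mod(e)^2))
  e <- sweep(e, 2, cn, "/")
  structure(list(entries = e, config = config, seed = as.integer(seed),
                 n_modes = n_modes, z_planes = z_planes),
            class = "transmission_matrix")
}

#' @export
print.transmission_matrix <- function(x, ...) {
  cat(sprintf("<transmission_matrix> %d pixels x %d modes, seed %d%s\n",
              nrow(x$entries), x$n_modes, x$seed,
              if (is.null(x$z_planes)) "" else
                sprintf(", %d z-planes", length(x$z_planes))))
  invisible(x)
}

#' Transmission matrix at one axial plane of a 3-D stack
#'
#' Composes the facet matrix with the free-space angular-spectrum
#' propagator to offset `z_um`, column by column.
#'
#' @param tm a `transmission_matrix`.
#' @param z_um axial offset in micrometers (0 returns the facet matrix).
#' @return a `transmission_matrix` at the requested plane.
#' @export
tm_at_plane <- function(tm, z_um) {
  stopifnot(inherits(tm, "transmission_matrix"))
  if (z_um == 0) return(tm)
  gs <- tm$config$grid_shape
  e <- tm$entries
  out <- e
  for (j in seq_len(ncol(e))) {
    f <- matrix(e[, j], gs[1], gs[2])
    out[, j] <- as.vector(propagate_angular_spectrum(f, z_um, tm$config))
  }
  tm2 <- tm
  tm2$entries <- out
  tm2
}

.check_target <- function(tm, target_pixel) {
  gs <- tm$config$grid_shape
  n_pix <- prod(gs)
  if (length(target_pixel) == 2) {
    target_pixel <- (target_pixel[2] - 1L) * gs[1] + target_pixel[1]
  }
  target_pixel <- as.integer(target_pixel)
  if (target_pixel < 1 || target_pixel > n_pix) stop("target pixel off grid")
  rc <- c((target_pixel - 1L) %% gs[1] + 1L, (target_pixel - 1L) %/% gs[1] + 1L)
  ctr <- (gs + 1) / 2
  r <- sqrt(sum((rc - ctr)^2))
  if (r > fov_radius_px(tm$config)) {
    stop("target pixel outside the fiber core aperture")
  }
  target_pixel
}

#' Phase-conjugate focusing mask
#'
#' Returns per-mode phases equal to the negated argument of the matrix row
#' of the target pixel, so all modes interfere constructively there
#' (phase-only conjugation).
#'
#' @param tm a `transmission_matrix`.
#' @param target_pixel linear pixel index or `(row, col)` pair; must lie
#'   inside the circular core aperture.
#' @return a `phase_mask` object (numeric phases in `[0, 2*pi)`).
#' @export
focus_mask <- function(tm, target_pixel) {
  stopifnot(inherits(tm, "transmission_matrix"))
  tp <- .check_target(tm, target_pixel)
  ph <- (-Arg(tm$entries[tp, ])) %% (2 * pi)
  structure(list(phases = ph, target_pixel = tp), class = "phase_mask")
}

#' Output intensity for a phase-only input
#'
#' Applies the unit-amplitude input `exp(i*phases)/sqrt(n_modes)` and
#' returns the output intensity image.
#'
#' @param tm a `transmission_matrix`.
#' @param mask a `phase_mask` or numeric phase vector of length `n_modes`.
#' @return non-negative matrix of shape `config$grid_shape`.
#' @export
apply_mask <- function(tm, mask) {
  ph <- if (inherits(mask, "phase_mask")) mask$phases else mask
  stopifnot(length(ph) == tm$n_modes)
  a <- exp(1i * ph) / sqrt(tm$n_modes)
  out <- tm$entries %*% a
  matrix(Mod(out)^2, tm$config$grid_shape[1], tm$config$grid_shape[2])
}

#' Focusing enhancement at a target pixel
#'
#' Ratio of the phase-conjugate focus intensity to the mean speckle
#' background at the same pixel. The background is the exact expectation of
#' the intensity over uniformly random input phases,
#' `sum(|t_k|^2) / n_modes` (cross terms average to zero). For an i.i.d.
#' circular-Gaussian matrix the expected enhancement is
#' `1 + (pi/4) * (n_modes - 1)`.
#'
#' @inheritParams focus_mask
#' @return list with `enhancement`, `focus_intensity`, `background`.
#' @export
focus_enhancement <- function(tm, target_pixel) {
  tp <- .check_target(tm, target_pixel)
  row <- tm$entries[tp, ]
  n <- length(row)
  i_focus <- sum(Mod(row))^2 / n
  bg <- sum(Mod(row)^2) / n
  list(enhancement = i_focus / bg, focus_intensity = i_focus, background = bg)
}

#' Theoretical phase-only enhancement
#' @param n_modes number of controlled modes.
#' @return `1 + (pi/4) * (n_modes - 1)`.
#' @export
enhancement_theory <- function(n_modes) 1 + pi / 4 * (n_modes - 1)
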