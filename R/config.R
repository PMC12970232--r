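#' Optical configuration of a fiber probe
#'
#' Bundles the physical parameters of the simulated multimode-fiber probe:
#' excitation wavelength, numerical aperture, core diameter, output-plane
#' sampling and grid size. The defaults describe the bench test probe
#' (NA 0.37 at 785 nm); the needle-integrated probe uses NA 0.22.
#'
#' @param wavelength_um excitation wavelength in micrometers (> 0).
#' @param na numerical aperture, strictly between 0 and 1.
#' @param core_diameter_um fiber core diameter in micrometers.
#' @param pixel_size_um output-plane sampling in micrometers; must satisfy
#'   the Nyquist bound `pixel_size <= wavelength / (2 * na)` so the
#'   diffraction-limited focus is resolvable. Defaults to the bound.
#' @param grid_shape integer pair, output-plane pixels (rows, cols). The
#'   default covers the core diameter at `pixel_size_um`.
#' @return an `optical_config` object (list).
#' @examples
#' cfg <- optical_config(0.785, 0.37, core_diameter_um = 125)
#' mode_count_estimate(cfg)
#' @export
optical_config <- function(wavelength_um = 0.785, na = 0.37,
                           core_diameter_um = 125,
                           pixel_size_um = NULL, grid_shape = NULL) {
  stopifnot(wavelength_um > 0, na > 0, na < 1, core_diameter_um > 0)
  nyq <- wavelength_um / (2 * na)
  if (is.null(pixel_size_um)) pixel_size_um <- nyq
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (pixel_size_um > nyq + 1e-12) {
    stop(sprintf("pixel_size_um (%.4g) violates the PSF Nyquist bound %.4g um",
                 pixel_size_um, nyq))
  }
  if (is.null(grid_shape)) {
    n <- ceiling(core_diameter_um / pixel_size_um)
    grid_shape <- c(n, n)
  }
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 2))
  structure(list(wavelength_um = wavelength_um, na = na,
                 core_diameter_um = core_diameter_um,
                 pixel_size_um = pixel_size_um, grid_shape = grid_shape),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(
    "<optical_config> lambda=%.3f um, NA=%.2f, core=%.0f um, pixel=%.3f um, grid=%dx%d\n",
    x$wavelength_um, x$na, x$core_diameter_um, x$pixel_size_um,
    x$grid_shape[1], x$grid_shape[2]))
  invisible(x)
}

#' Estimated guided-mode count of a step-index multimode fiber
#'
#' Uses the standard V-number estimate `(pi * d * NA / lambda)^2 / 2` for the
#' number of guided modes per polarization.
#'
#' @param config an [optical_config()].
#' @return estimated mode count (numeric, not rounded).
#' @export
mode_count_estimate <- function(config) {
  stopifnot(inherits(config, "optical_config"))
  (pi * config$core_diameter_um * config$na / config$wavelength_um)^2 / 2
}

#' Field-of-view radius of the core on the output grid, in pixels
#' @keywords internal
fov_radius_px <- function(config) {
  min(config$core_diameter_um / 2 / config$pixel_size_um,
      min(config$grid_shape) / 2)
}
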