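#' Free-space propagation by the angular-spectrum method
#'
#' Propagates a sampled complex field by `dz_um` along the optical axis.
#' Each plane-wave component acquires the phase
#' `exp(2i * pi * w * dz)` with `w = sqrt(1/lambda^2 - fx^2 - fy^2)`;
#' evanescent components (negative radicand) are set to zero so the
#' operator is unitary on the propagating band and exactly invertible by
#' propagating `-dz`.
#'
#' @param field complex (or numeric) matrix sampled at
#'   `config$pixel_size_um`.
#' @param dz_um propagation distance in micrometers (may be negative).
#' @param config an [optical_config()] providing wavelength and sampling.
#' @return complex matrix of the same shape.
#' @export
propagate_angular_spectrum <- function(field, dz_um, config) {
  stopifnot(inherits(config, "optical_config"))
  if (dz_um == 0) return(field + 0i)
  n <- nrow(field); m <- ncol(field)
  fy <- fft_freq(n, config$pixel_size_um)
  fx <- fft_freq(m, config$pixel_size_um)
  f2 <- outer(fy^2, fx^2, "+")
  w2 <- 1 / config$wavelength_um^2 - f2
  prop <- w2 > 0
  if (!any(prop)) {
    warning("no propagating components at this sampling; returning zeros")
  }
  h <- matrix(0i, n, m)
  h[prop] <- exp(2i * pi * sqrt(w2[prop]) * dz_um)
  ifft2(fft2(field) * h)
}
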