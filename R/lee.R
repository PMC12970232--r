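# Binary Lee holography: how a DMD (an amplitude-only, binary device)
# displays an arbitrary phase map. The phase is written onto a carrier
# grating; the first diffraction order of the binary pattern carries
# exp(i*phi).

#' Encode a phase map as a binary Lee hologram
#'
#' Classic binary amplitude encoding: `pattern = 1` where
#' `cos(2*pi*x/T + phi(x, y)) >= 0`, with the carrier running along image
#' columns and period `T = carrier_period` pixels.
#'
#' @param phases numeric matrix of target phases (radians) on the device
#'   grid.
#' @param carrier_period carrier period in pixels; must be at least 4 so
#'   the first order separates from DC and from its conjugate. The default
#'   17 is odd (so binarization harmonics that alias exactly onto the
#'   carrier have order >= 2*T-1) and incommensurate with power-of-two
#'   device grids, which empirically minimizes the pixel-quantization
#'   noise picked up by the demodulation window.
#' @return a `binary_hologram` object with fields `pattern` (0/1 integer
#'   matrix) and `carrier_period`.
#' @export
lee_encode <- function(phases, carrier_period = 17) {
  stopifnot(is.matrix(phases))
  if (carrier_period < 4) {
    stop("carrier_period < 4 pixels aliases the first diffraction order")
  }
  # sample at pixel centres (x + 1/2) so the comparison never lands on an
  # exact zero crossing, keeping the duty cycle exactly 1/2 on commensurate
  # grids
  x <- matrix(seq_len(ncol(phases)) - 0.5, nrow(phases), ncol(phases),
              byrow = TRUE)
  pat <- (cos(2 * pi * x / carrier_period + phases) >= 0) * 1L
  structure(list(pattern = pat, carrier_period = carrier_period),
            class = "binary_hologram")
}

#' Decode the phase carried by a binary Lee hologram
#'
#' Isolates the first diffraction order by Fourier filtering: a circular
#' window of radius half the carrier frequency centred on the carrier bin,
#' shifted to DC, then inverse transformed. Returns the recovered phase up
#' to one global offset (the demodulation has an arbitrary overall phase).
#'
#' @param holo a `binary_hologram` from [lee_encode()].
#' @return numeric matrix of recovered phases (radians, wrapped).
#' @export
lee_decode <- function(holo) {
  stopifnot(inherits(holo, "binary_hologram"))
  p <- holo$pattern
  n <- nrow(p); m <- ncol(p)
  fc <- 1 / holo$carrier_period          # cycles per pixel, along columns
  fy <- fft_freq(n); fx <- fft_freq(m)
  ic <- which.min(abs(fx - fc))          # nearest carrier column bin
  g <- fft2(p)
  d2 <- outer(fy^2, (fx - fx[ic])^2, "+")
  win <- d2 <= (fc / 2)^2
  g[!win] <- 0i
  s <- ifft2(g)
  # remove the exact (possibly fractional-bin) carrier in the space domain
  x <- matrix(seq_len(m) - 0.5, n, m, byrow = TRUE)
  Arg(s * exp(-2i * pi * x * fc))
}

#' RMS phase error between two wrapped phase maps, modulo a global offset
#' @param a,b phase matrices (radians).
#' @return root-mean-square wrapped difference after removing the best
#'   global offset.
#' @export
phase_rms_error <- function(a, b) {
  d <- Arg(exp(1i * (a - b)))
  off <- Arg(mean(exp(1i * d)))
  sqrt(mean(Arg(exp(1i * (d - off)))^2))
}
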