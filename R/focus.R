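# Brenner-function focal-plane selection. During a puncture the probe
# re-acquires focus by imaging several candidate planes, scoring each with
# the Brenner sharpness measure and locking onto the sharpest.

#' Brenner sharpness score
#'
#' Shift-2 squared-difference focus measure, summed over both axes,
#' restricted to pixel pairs that lie inside the field-of-view mask, and
#' divided by the number of contributing pairs. Adding a constant to the
#' image leaves the score unchanged; a constant image scores 0.
#'
#' @param image a `scan_image` or numeric matrix (at least 3 pixels per
#'   axis).
#' @param mask optional logical mask when `image` is a bare matrix.
#' @return non-negative scalar.
#' @export
brenner_score <- function(image, mask = NULL) {
  if (inherits(image, "scan_image")) {
    mask <- image$fov_mask
    image <- image$pixels
  }
  stopifnot(is.matrix(image), nrow(image) >= 3, ncol(image) >= 3)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  n <- nrow(image); m <- ncol(image)
  dh <- (image[, 3:m, drop = FALSE] - image[, 1:(m - 2), drop = FALSE])^2
  mh <- mask[, 3:m, drop = FALSE] & mask[, 1:(m - 2), drop = FALSE]
  dv <- (image[3:n, , drop = FALSE] - image[1:(n - 2), , drop = FALSE])^2
  mv <- mask[3:n, , drop = FALSE] & mask[1:(n - 2), , drop = FALSE]
  cnt <- sum(mh) + sum(mv)
  if (cnt == 0) stop("undefined Brenner score: empty field-of-view mask")
  (sum(dh[mh]) + sum(dv[mv])) / cnt
}

# image of a 3-D phantom as seen with the focal plane at z: every slice
# contributes, blurred by a geometric defocus kernel growing with its
# axial distance (half-angle NA), then the in-focus PSF is applied
.volume_view <- function(volume, z, config) {
  stopifnot(inherits(volume, "phantom"))
  zs <- volume$z_um
  if (is.null(zs)) stop("phantom has no axial dimension")
  px <- volume$pixel_size_um
  acc <- NULL
  for (k in seq_along(zs)) {
    sl <- volume$density[, , k]
    sig <- 0.5 * config$na * abs(z - zs[k]) / px
    sl <- gaussian_blur(sl, sig)
    acc <- if (is.null(acc)) sl else acc + sl
  }
  acc / length(zs)
}

#' Acquire a scan image of a 3-D phantom at a chosen focal plane
#'
#' @param tm a `transmission_matrix` or [optical_config()].
#' @param volume a 3-D [phantom()] (with `z_um`).
#' @param z focal-plane depth in micrometers; must lie within the volume's
#'   z range.
#' @param noise_peak,seed forwarded to the Poisson noise stage as in
#'   [acquire_scan()].
#' @return a `scan_image` at depth `z`.
#' @export
acquire_at_plane <- function(tm, volume, z, noise_peak = NULL, seed = 1L) {
  config <- if (inherits(tm, "transmission_matrix")) tm$config else tm
  zs <- volume$z_um
  if (z < min(zs) - 1e-9 || z > max(zs) + 1e-9) {
    stop(sprintf("focal plane z=%.3g um outside volume range [%.3g, %.3g]",
                 z, min(zs), max(zs)))
  }
  view <- .volume_view(volume, z, config)
  flat <- phantom(view, volume$pixel_size_um, label = volume$label,
                  seed = volume$seed)
  img <- acquire_scan(config, flat, mode = "ideal_psf",
                      noise_peak = noise_peak, seed = seed)
  img$z <- z
  img
}

#' Brenner-function autofocus over candidate planes
#'
#' Images the volume at every candidate plane, scores each image with
#' [brenner_score()], and returns the best plane; exact ties are broken
#' toward the smallest `|z|`.
#'
#' @inheritParams acquire_at_plane
#' @param z_candidates numeric vector of candidate depths (non-empty).
#' @return list with `z_best`, `image` (the winning `scan_image`), and
#'   `scores` (named by candidate depth).
#' @export
autofocus <- function(tm, volume, z_candidates, noise_peak = NULL,
                      seed = 1L) {
  if (length(z_candidates) < 1) {
    stop("autofocus needs at least one candidate plane")
  }
  imgs <- lapply(z_candidates, function(z) {
    acquire_at_plane(tm, volume, z, noise_peak = noise_peak, seed = seed)
  })
  scores <- vapply(imgs, brenner_score, numeric(1))
  best <- max(scores)
  el <- which(scores >= best * (1 - 1e-12))
  pick <- el[which.min(abs(z_candidates[el]))]
  list(z_best = z_candidates[pick], image = imgs[[pick]],
       scores = stats::setNames(scores, z_candidates))
}

#' Depth-indexed series of autofocused images along a puncture path
#'
#' At each depth the needle sees the volume in its own frame; the focus is
#' re-locked by [autofocus()] over `depth + focus_offsets_um` (clipped to
#' the volume's z range) and the winning image recorded.
#'
#' @inheritParams acquire_at_plane
#' @param depths strictly increasing puncture depths (micrometers); each
#'   must lie within the volume z range.
#' @param focus_offsets_um candidate plane offsets relative to each depth;
#'   defaults to the transmission matrix's `z_planes` if present, else
#'   `c(-10, -5, 0, 5, 10)`.
#' @return a `depth_series` object: list of `(z, image)` records.
#' @export
puncture_series <- function(tm, volume, depths, focus_offsets_um = NULL,
                            noise_peak = NULL, seed = 1L) {
  if (any(diff(depths) <= 0)) stop("depths must be strictly increasing")
  zs <- volume$z_um
  if (any(depths < min(zs) - 1e-9) || any(depths > max(zs) + 1e-9)) {
    stop("puncture depth outside the volume z range")
  }
  if (is.null(focus_offsets_um)) {
    focus_offsets_um <-
      if (inherits(tm, "transmission_matrix") && !is.null(tm$z_planes)) {
        tm$z_planes
      } else {
        c(-10, -5, 0, 5, 10)
      }
  }
  records <- lapply(seq_along(depths), function(i) {
    d <- depths[i]
    cand <- d + focus_offsets_um
    cand <- cand[cand >= min(zs) & cand <= max(zs)]
    if (length(cand) == 0) cand <- d
    af <- autofocus(tm, volume, cand, noise_peak = noise_peak,
                    seed = seed + i)
    list(z = d, image = af$image, z_focus = af$z_best)
  })
  structure(list(records = records, depths = depths),
            class = "depth_series")
}

#' @export
print.depth_series <- function(x, ...) {
  cat(sprintf("<depth_series> %d depths: %s um\n", length(x$records),
              paste(signif(x$depths, 4), collapse = ", ")))
  invisible(x)
}
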