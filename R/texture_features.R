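# The six per-image texture metrics: GLCM contrast and homogeneity
# (spatial domain), and average magnitude spectrum, high-frequency energy,
# spectral frequency contrast, spectral frequency variance (frequency
# domain, from the radial spectral-energy profile).

#' GLCM contrast and homogeneity
#'
#' Quantizes the image to `levels` gray bins inside the mask, accumulates
#' a symmetric co-occurrence matrix for each offset, averages the
#' normalized matrices, and returns
#' `contrast = sum P(i,j) (i-j)^2` and
#' `homogeneity = sum P(i,j) / (1 + |i-j|)`.
#'
#' @param image numeric matrix or `scan_image`.
#' @param levels number of gray levels (default 32).
#' @param offsets list of integer `(drow, dcol)` offsets; default the four
#'   distance-1 directions.
#' @param mask optional logical mask (pairs must lie fully inside).
#' @return named numeric vector `c(contrast =, homogeneity =)`.
#' @export
glcm_features <- function(image, levels = 32L,
                          offsets = list(c(0L, 1L), c(1L, 0L),
                                         c(1L, 1L), c(1L, -1L)),
                          mask = NULL) {
  if (inherits(image, "scan_image")) {
    mask <- image$fov_mask
    image <- image$pixels
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  if (sum(mask) < 2) stop("undefined GLCM: fewer than 2 pixel pairs in mask")
  q <- quantize_gray(image, levels, mask)
  n <- nrow(q); m <- ncol(q)
  acc <- matrix(0, levels, levels)
  used <- 0L
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1, 1 - dr):min(n, n - dr)
    c1 <- max(1, 1 - dc):min(m, m - dc)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    idx <- a[ok] * levels + b[ok] + 1L
    cnt <- tabulate(idx, nbins = levels * levels)
    g <- matrix(cnt, levels, levels, byrow = TRUE)  # rows = first level
    g <- g + t(g)                                    # symmetric
    acc <- acc + g / sum(g)
    used <- used + 1L
  }
  if (used == 0L) stop("undefined GLCM: fewer than 2 pixel pairs in mask")
  p <- acc / used
  i <- matrix(0:(levels - 1), levels, levels)
  j <- t(i)
  c(contrast = sum(p * (i - j)^2),
    homogeneity = sum(p / (1 + abs(i - j))))
}

#' Radial spectral-energy profile
#'
#' Masked pixels outside the field of view are filled with the masked
#' mean, the mean is subtracted (so DC vanishes), and `|FFT|^2` is summed
#' into integer-radius bins (frequency pixels), excluding DC.
#'
#' @param image numeric matrix or `scan_image`.
#' @param mask optional logical mask.
#' @return list with `radii` (integer bins) and `energy` (same length);
#'   `sum(energy)` equals the total non-DC spectral energy.
#' @export
radial_energy_profile <- function(image, mask = NULL) {
  if (inherits(image, "scan_image")) {
    mask <- image$fov_mask
    image <- image$pixels
  }
  n <- nrow(image); m <- ncol(image)
  if (!is.null(mask)) {
    mu <- mean(image[mask])
    image[!mask] <- mu
  }
  image <- image - mean(image)
  p <- Mod(fft2(image))^2
  ky <- c(seq(0, n %/% 2), seq(-((n - 1) %/% 2), -1))
  kx <- c(seq(0, m %/% 2), seq(-((m - 1) %/% 2), -1))
  r <- round(sqrt(outer(ky^2, kx^2, "+")))
  rmax <- max(r)
  e <- vapply(seq_len(rmax), function(k) sum(p[r == k]), numeric(1))
  list(radii = seq_len(rmax), energy = e)
}

#' Spectral texture metrics
#'
#' From the masked, mean-subtracted spectrum:
#' * `ams` -- mean non-DC magnitude `|F|`;
#' * `hfe` -- fraction of non-DC energy at radius beyond
#'   `hfe_cutoff_frac` of the Nyquist radius;
#' * `sfc` -- `ln(r95 / r50)`, where `r_q` is the smallest radius whose
#'   cumulative profile energy reaches `q` of the total;
#' * `sfv` -- `log10(Var_r[E] / Mean_r[E]^2 + eps)` over the radial
#'   profile.
#'
#' A zero-energy image returns epsilon-guarded sentinels with
#' `attr(, "degenerate") = TRUE`.
#'
#' @param image numeric matrix or `scan_image`.
#' @param hfe_cutoff_frac high-frequency cutoff as a fraction of the
#'   Nyquist radius (default 0.25).
#' @param mask optional logical mask.
#' @param eps relative variance guard (default 1e-12).
#' @return named numeric vector `c(ams, hfe, sfc, sfv)`.
#' @export
spectral_metrics <- function(image, hfe_cutoff_frac = 0.25, mask = NULL,
                             eps = 1e-12) {
  if (inherits(image, "scan_image")) {
    mask <- image$fov_mask
    image <- image$pixels
  }
  n <- nrow(image); m <- ncol(image)
  if (!is.null(mask)) {
    mu <- mean(image[mask])
    image[!mask] <- mu
  }
  image <- image - mean(image)
  f <- fft2(image)
  magsum <- sum(Mod(f)) - Mod(f[1, 1])
  ams <- magsum / (length(f) - 1)
  prof <- radial_energy_profile(image)
  e <- prof$energy
  tot <- sum(e)
  if (tot <= 0) {
    out <- c(ams = 0, hfe = 0, sfc = 0, sfv = log10(eps))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  r_nyq <- floor(min(n, m) / 2)
  hfe <- sum(e[prof$radii > hfe_cutoff_frac * r_nyq]) / tot
  cum <- cumsum(e) / tot
  r50 <- prof$radii[which(cum >= 0.5)[1]]
  r95 <- prof$radii[which(cum >= 0.95)[1]]
  sfc <- log(r95 / r50)
  mu_e <- mean(e)
  sfv <- log10(stats::var(e) / mu_e^2 + eps)
  c(ams = ams, hfe = hfe, sfc = sfc, sfv = sfv)
}

#' Per-image metric table for a labeled image set
#'
#' @param images list of numeric matrices (or `scan_image`s), or a
#'   `phantom_cohort`.
#' @param labels character vector of class labels (ignored for a cohort).
#' @param levels,offsets GLCM settings, see [glcm_features()].
#' @param hfe_cutoff_frac see [spectral_metrics()].
#' @param mask optional shared logical mask.
#' @return a `metric_table`: data.frame with columns `id`, `label`,
#'   `contrast`, `homogeneity`, `ams`, `hfe`, `sfc`, `sfv`.
#' @export
feature_table <- function(images, labels = NULL, levels = 32L,
                          offsets = list(c(0L, 1L), c(1L, 0L),
                                         c(1L, 1L), c(1L, -1L)),
                          hfe_cutoff_frac = 0.25, mask = NULL) {
  if (inherits(images, "phantom_cohort")) {
    labels <- images$labels
    images <- images$images
  }
  stopifnot(length(labels) == length(images))
  rows <- lapply(seq_along(images), function(i) {
    g <- glcm_features(images[[i]], levels, offsets, mask)
    s <- spectral_metrics(images[[i]], hfe_cutoff_frac, mask)
    data.frame(id = i, label = labels[i],
               contrast = g[["contrast"]], homogeneity = g[["homogeneity"]],
               ams = s[["ams"]], hfe = s[["hfe"]], sfc = s[["sfc"]],
               sfv = s[["sfv"]], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("metric_table", "data.frame")
  tab
}

#' Min-max normalize metric columns over the pooled table
#'
#' Each selected column is mapped through `(x - min) / (max - min)` using
#' the pooled (all-group) extremes; the constants are recorded in
#' `attr(, "norm_constants")`. A constant column is an error.
#'
#' @param table a `metric_table` (or data.frame).
#' @param columns columns to normalize; default the six metrics.
#' @return the table with normalized columns.
#' @export
minmax_normalize <- function(table,
                             columns = c("contrast", "homogeneity", "ams",
                                         "hfe", "sfc", "sfv")) {
  consts <- list()
  for (cl in columns) {
    x <- table[[cl]]
    lo <- min(x); hi <- max(x)
    if (hi <= lo) stop(sprintf("degenerate column '%s': constant values", cl))
    table[[cl]] <- (x - lo) / (hi - lo)
    consts[[cl]] <- c(min = lo, max = hi)
  }
  attr(table, "norm_constants") <- consts
  table
}
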