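# Unsupervised dual-feature tumor/normal discrimination: a gray-level
# intensity-distribution view and a Canny/Sobel edge view, each PCA-reduced
# and clustered with K-means (k = 2); cluster indices are aligned to the
# ground truth and the two views are combined with an OR-toward-tumor rule
# that can only raise sensitivity.

#' Gray-level intensity-distribution features
#'
#' 64-bin normalized histogram of gray values inside the mask (sums to 1).
#' For cohort use, pass a shared `range` so absolute brightness differences
#' between images are preserved.
#'
#' @param image numeric matrix.
#' @param bins number of histogram bins (default 64).
#' @param mask optional logical mask.
#' @param range gray range `c(lo, hi)` defining the bins; defaults to the
#'   image's own range.
#' @return numeric vector of length `bins`, summing to 1.
#' @export
intensity_features <- function(image, bins = 64L, mask = NULL,
                               range = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  v <- image[mask]
  if (length(v) == 0) stop("empty field-of-view mask")
  if (is.null(range)) range <- c(min(v), max(v))
  if (range[2] <= range[1]) {
    h <- numeric(bins); h[1] <- 1
    return(h)
  }
  b <- pmin(pmax(floor((v - range[1]) / (range[2] - range[1]) * bins),
                 0), bins - 1L)
  tabulate(b + 1L, nbins = bins) / length(v)
}

#' Sobel gradients
#' @param image numeric matrix.
#' @return list with `gx`, `gy`, `mag` matrices.
#' @keywords internal
sobel_gradients <- function(image) {
  n <- nrow(image); m <- ncol(image)
  ri <- function(d) pmin(pmax(seq_len(n) + d, 1L), n)
  ci <- function(d) pmin(pmax(seq_len(m) + d, 1L), m)
  s <- function(dr, dc) image[ri(dr), ci(dc), drop = FALSE]
  gx <- (s(-1, 1) + 2 * s(0, 1) + s(1, 1)) -
        (s(-1, -1) + 2 * s(0, -1) + s(1, -1))
  gy <- (s(1, -1) + 2 * s(1, 0) + s(1, 1)) -
        (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Canny edge detector
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and hysteresis thresholding. Thresholds
#' derive from the gradient-magnitude distribution: `high` is its
#' `high_quantile` (default 90th percentile), `low = low_frac * high`.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian smoothing (default 1).
#' @param high_quantile,low_frac threshold rule.
#' @return logical edge matrix.
#' @export
canny_edges <- function(image, sigma = 1, high_quantile = 0.9,
                        low_frac = 0.4) {
  sm <- gaussian_blur(image, sigma)
  g <- sobel_gradients(sm)
  mag <- g$mag
  n <- nrow(mag); m <- ncol(mag)
  ang <- atan2(g$gy, g$gx)              # [-pi, pi]
  sector <- (round(ang / (pi / 4)) %% 4)  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  pad <- matrix(0, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- mag
  at <- function(dr, dc) pad[(2 + dr):(n + 1 + dr), (2 + dc):(m + 1 + dc)]
  n1 <- matrix(0, n, m); n2 <- matrix(0, n, m)
  sel <- sector == 0; n1[sel] <- at(0, 1)[sel];  n2[sel] <- at(0, -1)[sel]
  sel <- sector == 1; n1[sel] <- at(1, 1)[sel];  n2[sel] <- at(-1, -1)[sel]
  sel <- sector == 2; n1[sel] <- at(1, 0)[sel];  n2[sel] <- at(-1, 0)[sel]
  sel <- sector == 3; n1[sel] <- at(1, -1)[sel]; n2[sel] <- at(-1, 1)[sel]
  keep <- mag >= n1 & mag >= n2
  high <- stats::quantile(mag, high_quantile, names = FALSE)
  if (high <= 0) return(matrix(FALSE, n, m))
  low <- low_frac * high
  strong <- keep & mag >= high
  weak <- keep & mag >= low
  # hysteresis: grow strong edges through weak pixels (8-connected)
  edges <- strong
  repeat {
    padE <- matrix(FALSE, n + 2, m + 2)
    padE[2:(n + 1), 2:(m + 1)] <- edges
    nb <- matrix(FALSE, n, m)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- nb | padE[(2 + dr):(n + 1 + dr), (2 + dc):(m + 1 + dc)]
    }
    grown <- edges | (weak & nb)
    if (identical(grown, edges)) break
    edges <- grown
  }
  edges
}

#' Edge-structure features
#'
#' Concatenates the overall Canny edge density, edge densities in 8 equal
#' radial annuli of the field of view, and a 16-bin histogram of Sobel
#' gradient magnitudes (normalized to sum 1).
#'
#' @param image numeric matrix.
#' @param mask optional logical field-of-view mask.
#' @param n_annuli number of radial annuli (default 8).
#' @param grad_bins Sobel histogram bins (default 16).
#' @param sigma,high_quantile,low_frac forwarded to [canny_edges()].
#' @return numeric feature vector of length `1 + n_annuli + grad_bins`.
#' @export
edge_features <- function(image, mask = NULL, n_annuli = 8L,
                          grad_bins = 16L, sigma = 1,
                          high_quantile = 0.9, low_frac = 0.4) {
  n <- nrow(image); m <- ncol(image)
  if (is.null(mask)) mask <- circular_mask(c(n, m))
  ed <- canny_edges(image, sigma, high_quantile, low_frac)
  overall <- mean(ed[mask])
  cy <- (n + 1) / 2; cx <- (m + 1) / 2
  r <- sqrt(outer((seq_len(n) - cy)^2, (seq_len(m) - cx)^2, "+"))
  rmax <- min(n, m) / 2
  ann <- vapply(seq_len(n_annuli), function(k) {
    ring <- mask & r >= (k - 1) / n_annuli * rmax & r < k / n_annuli * rmax
    if (any(ring)) mean(ed[ring]) else 0
  }, numeric(1))
  gm <- sobel_gradients(image)$mag[mask]
  hi <- max(gm)
  gh <- if (hi > 0) {
    b <- pmin(floor(gm / hi * grad_bins), grad_bins - 1L)
    tabulate(b + 1L, nbins = grad_bins) / length(gm)
  } else {
    h <- numeric(grad_bins); h[1] <- 1; h
  }
  c(edge_density = overall,
    stats::setNames(ann, paste0("annulus_", seq_len(n_annuli))),
    stats::setNames(gh, paste0("grad_", seq_len(grad_bins))))
}

#' Build the standardized feature matrix for one view
#'
#' Images are resized to `resize_px` for cohort uniformity; features are
#' extracted per image and columns standardized to mean 0, sd 1
#' (zero-variance columns are dropped).
#'
#' @param images list of numeric matrices or a `phantom_cohort`.
#' @param view `"intensity"` or `"edge"`.
#' @param resize_px working image size (default 128).
#' @return a `feature_matrix`: standardized numeric matrix with
#'   `attr(, "view")`.
#' @export
feature_matrix <- function(images, view = c("intensity", "edge"),
                           resize_px = 128L) {
  view <- match.arg(view)
  if (inherits(images, "phantom_cohort")) images <- images$images
  imgs <- lapply(images, function(im) {
    if (inherits(im, "scan_image")) im <- im$pixels
    if (nrow(im) != resize_px || ncol(im) != resize_px) {
      im <- resize_image(im, c(resize_px, resize_px))
    }
    im
  })
  mask <- circular_mask(c(resize_px, resize_px))
  feats <- if (view == "intensity") {
    rng <- range(unlist(lapply(imgs, function(im) range(im[mask]))))
    t(vapply(imgs, intensity_features, numeric(64), bins = 64L,
             mask = mask, range = rng))
  } else {
    t(vapply(imgs, edge_features, numeric(25), mask = mask))
  }
  sds <- apply(feats, 2, stats::sd)
  keep <- sds > 0
  z <- scale(feats[, keep, drop = FALSE])
  attr(z, "view") <- view
  class(z) <- c("feature_matrix", class(z))
  z
}

#' PCA reduction followed by K-means (k = 2)
#'
#' @param x standardized feature matrix (rows = images).
#' @param n_components PCA components to keep (default 10, capped at
#'   `min(rows - 1, cols)`).
#' @param seed seed for the K-means restarts (20 restarts).
#' @return integer cluster labels in `{1, 2}`.
#' @export
pca_kmeans <- function(x, n_components = 10L, seed = 0L) {
  x <- unclass(x)
  if (nrow(x) < 2) stop("need at least 2 rows to form 2 clusters")
  nc <- min(n_components, nrow(x) - 1L, ncol(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(nc), drop = FALSE]
  set.seed(as.integer(seed))
  km <- stats::kmeans(scores, centers = 2L, nstart = 20L, iter.max = 100L)
  km$cluster
}

#' Align predicted cluster indices with ground-truth labels
#'
#' Cluster indices are arbitrary; the permutation maximizing accuracy is
#' chosen. Sensitivity is tumor recall; specificity is normal recall.
#'
#' @param pred integer or character predicted labels.
#' @param truth character ground truth (`"normal"`/`"tumor"`).
#' @return list with `labels` (aligned character vector), `accuracy`,
#'   `sensitivity`, `specificity`, and `confusion` (2x2 table).
#' @export
align_labels <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  u <- sort(unique(pred))
  if (length(u) > 2) stop("more than two predicted labels")
  evaluate <- function(lab) {
    acc <- mean(lab == truth)
    sens <- if (any(truth == "tumor")) {
      mean(lab[truth == "tumor"] == "tumor")
    } else NA_real_
    spec <- if (any(truth == "normal")) {
      mean(lab[truth == "normal"] == "normal")
    } else NA_real_
    list(labels = lab, accuracy = acc, sensitivity = sens,
         specificity = spec,
         confusion = table(truth = truth, pred = factor(lab, c("normal", "tumor"))))
  }
  m1 <- c("normal", "tumor"); m2 <- rev(m1)
  lab1 <- m1[match(pred, u)]
  if (length(u) == 1) lab1 <- rep(m1[1], length(pred))
  lab2 <- m2[match(pred, u)]
  if (length(u) == 1) lab2 <- rep(m2[1], length(pred))
  e1 <- evaluate(lab1); e2 <- evaluate(lab2)
  if (e1$accuracy >= e2$accuracy) e1 else e2
}

#' Combine two aligned label vectors across views
#'
#' `"or_tumor"` labels an image tumor when either view does (never lowers
#' sensitivity); `"and_tumor"` requires both; `"majority"` with two views
#' reduces to `"and_tumor"` plus agreement.
#'
#' @param labels_intensity,labels_edge aligned character label vectors.
#' @param rule combination rule.
#' @return character label vector.
#' @export
dual_combine <- function(labels_intensity, labels_edge,
                         rule = c("or_tumor", "and_tumor")) {
  rule <- match.arg(rule)
  if (length(labels_intensity) != length(labels_edge)) {
    stop("unaligned inputs: label vectors differ in length")
  }
  both <- cbind(labels_intensity, labels_edge)
  if (!all(both %in% c("normal", "tumor"))) {
    stop("labels must be 'normal'/'tumor' (aligned)")
  }
  tum <- if (rule == "or_tumor") {
    labels_intensity == "tumor" | labels_edge == "tumor"
  } else {
    labels_intensity == "tumor" & labels_edge == "tumor"
  }
  ifelse(tum, "tumor", "normal")
}

#' Dual-view discrimination pipeline
#'
#' Runs both feature views through PCA + K-means, aligns each to the
#' ground truth, combines them, and evaluates.
#'
#' @param images list of matrices or `phantom_cohort`.
#' @param truth ground-truth labels (taken from the cohort if omitted).
#' @param seed clustering seed.
#' @param rule combination rule for [dual_combine()].
#' @param n_components PCA components per view.
#' @param resize_px working image size.
#' @return a `cluster_result` list: per-view aligned labels and scores,
#'   combined labels and scores.
#' @export
discriminate_cohort <- function(images, truth = NULL, seed = 0L,
                                rule = "or_tumor", n_components = 10L,
                                resize_px = 128L) {
  if (inherits(images, "phantom_cohort") && is.null(truth)) {
    truth <- images$labels
  }
  fi <- feature_matrix(images, "intensity", resize_px)
  fe <- feature_matrix(images, "edge", resize_px)
  discriminate_views(fi, fe, truth, seed = seed, rule = rule,
                     n_components = n_components)
}

#' Discrimination from precomputed feature views
#'
#' Same contract as [discriminate_cohort()] but starting from two
#' [feature_matrix()] objects (useful to rerun clustering seeds without
#' re-extracting features).
#'
#' @param fi,fe intensity and edge `feature_matrix` objects.
#' @inheritParams discriminate_cohort
#' @return a `cluster_result` list.
#' @export
discriminate_views <- function(fi, fe, truth, seed = 0L,
                               rule = "or_tumor", n_components = 10L) {
  ai <- align_labels(pca_kmeans(fi, n_components, seed), truth)
  ae <- align_labels(pca_kmeans(fe, n_components, seed + 1L), truth)
  comb <- dual_combine(ai$labels, ae$labels, rule)
  acc <- mean(comb == truth)
  sens <- mean(comb[truth == "tumor"] == "tumor")
  spec <- mean(comb[truth == "normal"] == "normal")
  structure(list(intensity = ai, edge = ae,
                 combined = list(labels = comb, accuracy = acc,
                                 sensitivity = sens, specificity = spec),
                 rule = rule, seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> intensity acc %.3f | edge acc %.3f | combined acc %.3f sens %.3f spec %.3f (%s)\n",
    x$intensity$accuracy, x$edge$accuracy, x$combined$accuracy,
    x$combined$sensitivity, x$combined$specificity, x$rule))
  invisible(x)
}
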