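# Dual-view PCA/K-means discrimination.

# independent straightforward recomputation of the edge-feature definitions
edge_oracle <- function(img, mask) {
  ed <- canny_edges(img)                # operator itself tested separately
  n <- nrow(img); m <- ncol(img)
  overall <- sum(ed & mask) / sum(mask)
  cy <- (n + 1) / 2; cx <- (m + 1) / 2
  rmax <- min(n, m) / 2
  ann <- numeric(8)
  cnt <- numeric(8)
  hit <- numeric(8)
  for (r in 1:n) for (cc in 1:m) {
    if (!mask[r, cc]) next
    rad <- sqrt((r - cy)^2 + (cc - cx)^2)
    k <- floor(rad / rmax * 8) + 1
    if (k > 8) next
    cnt[k] <- cnt[k] + 1
    if (ed[r, cc]) hit[k] <- hit[k] + 1
  }
  ann <- ifelse(cnt > 0, hit / cnt, 0)
  # plain-loop Sobel magnitude histogram
  gm <- c()
  for (r in 1:n) for (cc in 1:m) {
    if (!mask[r, cc]) next
    rm1 <- max(r - 1, 1); rp1 <- min(r + 1, n)
    cm1 <- max(cc - 1, 1); cp1 <- min(cc + 1, m)
    gx <- (img[rm1, cp1] + 2 * img[r, cp1] + img[rp1, cp1]) -
          (img[rm1, cm1] + 2 * img[r, cm1] + img[rp1, cm1])
    gy <- (img[rp1, cm1] + 2 * img[rp1, cc] + img[rp1, cp1]) -
          (img[rm1, cm1] + 2 * img[rm1, cc] + img[rm1, cp1])
    gm <- c(gm, sqrt(gx^2 + gy^2))
  }
  hi <- max(gm)
  gh <- numeric(16)
  for (g in gm) {
    b <- min(floor(g / hi * 16), 15) + 1
    gh[b] <- gh[b] + 1
  }
  unname(c(overall, ann, gh / length(gm)))
}

test_that("intensity features: degenerate and generic histograms", {
  h <- intensity_features(matrix(5, 16, 16))
  expect_equal(h[1], 1)
  expect_equal(sum(h), 1)
  set.seed(1)
  img <- matrix(runif(256), 16, 16)
  h2 <- intensity_features(img)
  expect_equal(sum(h2), 1)
  expect_length(h2, 64)
  expect_error(intensity_features(img, mask = matrix(FALSE, 16, 16)),
               "empty")
})

test_that("edge features: constant image, checkerboard, oracle match", {
  f0 <- edge_features(matrix(2, 32, 32))
  expect_equal(unname(f0[1:9]), rep(0, 9))
  cb <- matrix((outer(1:32, 1:32, "+") %% 2), 32, 32)
  fc <- edge_features(cb)
  expect_gt(fc[["edge_density"]], 0)
  mask <- circular_mask(c(32, 32))
  for (s in 1:3) {
    set.seed(s)
    img <- gaussian_blur(matrix(runif(1024), 32, 32), 1)
    got <- unname(edge_features(img, mask = mask))
    expect_equal(got, edge_oracle(img, mask), tolerance = 1e-10)
  }
})

test_that("pca_kmeans: separation, duplicates, determinism", {
  set.seed(5)
  x <- rbind(matrix(rnorm(50 * 4), 50, 4),
             matrix(rnorm(50 * 4, mean = 10), 50, 4))
  cl <- pca_kmeans(x, n_components = 3, seed = 1)
  expect_equal(length(unique(cl[1:50])), 1)
  expect_equal(length(unique(cl[51:100])), 1)
  expect_false(cl[1] == cl[51])
  # duplicated rows get identical labels
  xd <- rbind(x, x[1, , drop = FALSE])
  cld <- pca_kmeans(xd, seed = 2)
  expect_equal(cld[101], cld[1])
  expect_identical(pca_kmeans(x, seed = 3), pca_kmeans(x, seed = 3))
  expect_error(pca_kmeans(x[1, , drop = FALSE]), "2 rows")
})

test_that("align_labels: identity, complement, random baseline", {
  truth <- rep(c("normal", "tumor"), each = 30)
  a <- align_labels(ifelse(truth == "tumor", 2, 1), truth)
  expect_equal(a$accuracy, 1)
  expect_equal(a$labels, truth)
  b <- align_labels(ifelse(truth == "tumor", 1, 2), truth)
  expect_equal(b$accuracy, 1)           # permutation-corrected
  set.seed(42)
  truth387 <- rep(c("normal", "tumor"), c(194, 193))
  accs <- vapply(1:20, function(i) {
    align_labels(sample(1:2, 387, TRUE), truth387)$accuracy
  }, numeric(1))
  expect_lt(max(abs(accs - 0.5)), 0.12)  # ~4 binomial sd
  expect_gte(min(accs), 0.5)             # alignment never below chance
  expect_error(align_labels(1:3, truth), "length")
})

test_that("dual_combine rule and constructed complementarity", {
  expect_equal(dual_combine("tumor", "normal"), "tumor")
  expect_equal(dual_combine("normal", "normal"), "normal")
  expect_equal(dual_combine("tumor", "normal", rule = "and_tumor"),
               "normal")
  expect_error(dual_combine(c("tumor"), c("tumor", "normal")), "unaligned")
  # disjoint error sets: combination strictly beats both views
  truth <- rep(c("normal", "tumor"), each = 50)
  va <- truth; va[51:55] <- "normal"     # view A misses tumors 1-5
  vb <- truth; vb[56:60] <- "normal"     # view B misses tumors 6-10
  sens <- function(lab) mean(lab[truth == "tumor"] == "tumor")
  comb <- dual_combine(va, vb)
  expect_gt(sens(comb), max(sens(va), sens(vb)))
  expect_equal(sens(comb), 1)
})

test_that("dual-view pipeline separates the phantom cohort", {
  ch <- small_cohort()
  res <- discriminate_cohort(ch, seed = 0)
  expect_gte(res$intensity$accuracy, 0.85)
  expect_gte(res$edge$accuracy, 0.85)
  expect_gte(res$combined$sensitivity,
             max(res$intensity$sensitivity, res$edge$sensitivity))
  # determinism given (cohort seed, clustering seed)
  res2 <- discriminate_cohort(ch, seed = 0)
  expect_identical(res2$combined$labels, res$combined$labels)
})

test_that("embed_2d is deterministic, well-shaped, and separates blobs", {
  set.seed(9)
  x <- rbind(matrix(rnorm(20 * 5), 20, 5),
             matrix(rnorm(20 * 5, mean = 8), 20, 5))
  y1 <- embed_2d(x, seed = 4, n_iter = 150)
  y2 <- embed_2d(x, seed = 4, n_iter = 150)
  expect_identical(y1, y2)
  expect_equal(dim(y1), c(40L, 2L))
  within <- mean(dist(y1[1:20, ])) + mean(dist(y1[21:40, ]))
  between <- mean(as.matrix(dist(y1))[1:20, 21:40])
  expect_gt(between, within / 2)         # clusters stay separated
  expect_error(embed_2d(x[1:3, ]), "at least 5")
})
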