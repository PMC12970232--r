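# The six texture metrics; brute-force oracles live in helper-oracles.R.

test_that("GLCM basics: constant image and the 2x2 checkerboard", {
  g <- glcm_features(matrix(3.3, 8, 8))
  expect_equal(unname(g), c(0, 1))
  cb <- matrix(c(0, 1, 1, 0), 2, 2)
  g2 <- glcm_features(cb, levels = 2L, offsets = list(c(0L, 1L)))
  # 4 symmetric pairs, all (0,1)/(1,0): contrast 1, homogeneity 0.5
  expect_equal(g2[["contrast"]], 1)
  expect_equal(g2[["homogeneity"]], 0.5)
})

test_that("GLCM equals the brute-force pair oracle on random images", {
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (s in 1:50) {
    set.seed(s)
    img <- matrix(runif(64), 8, 8)
    expect_equal(glcm_features(img, 8L, offs),
                 glcm_oracle_acc(img, 8, offs), tolerance = 1e-12)
  }
  # masked variant
  set.seed(99)
  img <- matrix(runif(100), 10, 10)
  msk <- circular_mask(c(10, 10))
  expect_equal(glcm_features(img, 8L, offs, mask = msk),
               glcm_oracle_acc(img, 8, offs, mask = msk), tolerance = 1e-12)
  expect_error(glcm_features(matrix(1, 3, 3),
                             mask = matrix(FALSE, 3, 3)), "undefined")
})

test_that("radial profile: cosine ring, Parseval, rotation", {
  n <- 32
  x <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  img <- cos(2 * pi * 8 * x / n)
  prof <- radial_energy_profile(img)
  expect_equal(prof$radii[which.max(prof$energy)], 8)
  set.seed(1)
  r <- matrix(rnorm(n * n), n, n)
  pr <- radial_energy_profile(r)
  f <- fft(r - mean(r))
  expect_equal(sum(pr$energy), sum(Mod(f)^2) - Mod(f[1, 1])^2,
               tolerance = 1e-6)
  rot <- t(r)[n:1, ]                      # 90 degree rotation
  expect_equal(radial_energy_profile(rot)$energy, pr$energy,
               tolerance = 1e-9)
})

test_that("spectral metrics: ring, zero image, white vs low-pass", {
  n <- 32
  x <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  ring <- cos(2 * pi * 8 * x / n)
  sm <- spectral_metrics(ring)
  expect_equal(sm[["sfc"]], 0)            # r50 = r95 on a single ring
  z <- spectral_metrics(matrix(0, 16, 16))
  expect_equal(z[["ams"]], 0)
  expect_equal(z[["sfv"]], log10(1e-12))
  expect_true(isTRUE(attr(z, "degenerate")))
  for (s in 1:20) {
    set.seed(s)
    w <- matrix(rnorm(64 * 64), 64, 64)
    lp <- gaussian_blur(w, 2)
    expect_gt(spectral_metrics(w)[["hfe"]], spectral_metrics(lp)[["hfe"]])
  }
})

test_that("spectral metrics are offset- and rotation-invariant and sfc >= 0", {
  set.seed(7)
  for (i in 1:10) {
    img <- matrix(runif(48 * 48), 48, 48)
    a <- spectral_metrics(img)
    b <- spectral_metrics(img + 3.7)
    expect_equal(a, b, tolerance = 1e-9)
    rot <- t(img)[48:1, ]
    expect_equal(spectral_metrics(rot), a, tolerance = 1e-9)
    expect_gte(a[["sfc"]], 0)
  }
})

test_that("min-max normalization contract", {
  df <- data.frame(id = 1:3, label = "normal",
                   contrast = c(2, 4, 6), homogeneity = c(1, 2, 4),
                   ams = c(0, 1, 2), hfe = c(0.1, 0.2, 0.3),
                   sfc = c(5, 1, 3), sfv = c(-1, 0, 1))
  nm <- minmax_normalize(df)
  expect_equal(nm$contrast, c(0, 0.5, 1))
  expect_equal(order(nm$sfc), order(df$sfc))   # monotone transform
  nm2 <- minmax_normalize(nm)
  expect_equal(nm2$contrast, nm$contrast)      # idempotent
  df$ams <- 1
  expect_error(minmax_normalize(df), "degenerate")
})

test_that("feature_table shape, determinism and order covariance", {
  ch <- small_cohort()
  tab <- small_metric_table()
  expect_equal(nrow(tab), length(ch$images))
  expect_true(all(c("contrast", "homogeneity", "ams", "hfe", "sfc",
                    "sfv") %in% names(tab)))
  sub <- feature_table(ch$images[c(3, 1)], ch$labels[c(3, 1)])
  expect_equal(sub$contrast, tab$contrast[c(3, 1)], tolerance = 1e-12)
  expect_equal(sub$label, tab$label[c(3, 1)])
})

test_that("tumor cohort means exceed normal on the spectral metrics", {
  tab <- small_metric_table()
  m <- aggregate(tab[, c("ams", "hfe", "sfc", "sfv")],
                 list(label = tab$label), mean)
  tum <- m[m$label == "tumor", -1]
  nor <- m[m$label == "normal", -1]
  expect_true(all(tum > nor))
})
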