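# Point-scan acquisition, reconstruction, Brenner autofocus, puncture
# series.

test_that("uniform phantom gives a flat field inside the mask", {
  cfg <- optical_config(0.785, 0.37, core_diameter_um = 25.6,
                        pixel_size_um = 0.4, grid_shape = c(64, 64))
  ph <- phantom(matrix(0.7, 64, 64), 0.4)
  im <- acquire_scan(cfg, ph, mode = "ideal_psf")
  v <- im$pixels[im$fov_mask]
  expect_lt(diff(range(v)) / mean(v), 1e-9)
  # linearity: doubling brightness doubles the image
  ph2 <- phantom(2 * ph$density, 0.4)
  im2 <- acquire_scan(cfg, ph2, mode = "ideal_psf")
  expect_equal(im2$pixels, 2 * im$pixels, tolerance = 1e-12)
})

test_that("two points at the Rayleigh distance show a dip", {
  # independent oracle: numeric superposition of two 1-D Airy intensity
  # profiles sampled finely
  lam <- 0.785; na <- 0.37
  r0 <- 0.61 * lam / na
  airy1 <- function(x) {
    v <- 3.8317060 * abs(x) / r0
    ifelse(v < 1e-9, 1, (2 * besselJ(v, 1) / v)^2)
  }
  sep <- 1.3
  prof <- function(x) airy1(x - sep / 2) + airy1(x + sep / 2)
  expect_lt(prof(0), prof(sep / 2))     # oracle confirms the dip
  # the simulated scan reproduces it
  cfg <- optical_config(lam, na, core_diameter_um = 16,
                        pixel_size_um = 0.2, grid_shape = c(65, 65))
  tp <- two_point_target(1.3, 0.2, c(65, 65))
  im <- acquire_scan(cfg, tp, mode = "ideal_psf")
  row <- im$pixels[33, ]
  mid <- row[33]
  pk <- max(row)
  expect_lt(mid, pk)
})

test_that("speckle-mode acquisition is linear and deterministic", {
  cfg <- optical_config(0.785, 0.37, core_diameter_um = 8,
                        pixel_size_um = 0.4, grid_shape = c(12, 12))
  tm <- generate_tm(cfg, 48, seed = 5)
  set.seed(31)
  d <- matrix(runif(144), 12, 12)
  ph <- phantom(d, 0.4)
  im1 <- acquire_scan(tm, ph, mode = "speckle")
  im2 <- acquire_scan(tm, ph, mode = "speckle")
  expect_identical(im1$pixels, im2$pixels)
  im3 <- acquire_scan(tm, phantom(3 * d, 0.4), mode = "speckle")
  expect_equal(im3$pixels, 3 * im1$pixels, tolerance = 1e-12)
})

test_that("reconstruct honours layout, denoise and the circular crop", {
  sig <- as.numeric(1:64)
  im <- reconstruct(sig, c(8, 8), pixel_size_um = 1, denoise = "none")
  ref <- matrix(sig, 8, 8)
  expect_equal(im$pixels[im$fov_mask], ref[im$fov_mask])
  expect_true(all(im$pixels[!im$fov_mask] == 0))
  # impulse on a flat field is removed by the 3x3 median
  flat <- rep(1, 81)
  flat[41] <- 100                        # centre of a 9x9 grid
  imd <- reconstruct(flat, c(9, 9), denoise = "median")
  expect_equal(imd$pixels[5, 5], 1)
  expect_error(reconstruct(1:10, c(4, 4)), "does not match")
})

test_that("Brenner score matches hand summation and its invariances", {
  img <- matrix(0:3, 4, 4, byrow = TRUE)  # I[, j] = j-1: horizontal ramp
  # horizontal pairs per row: (2-0)^2 + (3-1)^2 = 8; 4 rows -> 32
  # vertical pairs contribute 0; pair count = 8 + 8
  expect_equal(brenner_score(img), 32 / 16)
  expect_equal(brenner_score(matrix(5, 8, 8)), 0)
  set.seed(2)
  tex <- matrix(runif(64 * 64), 64, 64)
  expect_equal(brenner_score(tex), brenner_score(tex + 11.5))
  expect_error(brenner_score(tex, mask = matrix(FALSE, 64, 64)), "mask")
})

test_that("Brenner score strictly decreases under increasing blur", {
  set.seed(4)
  tex <- matrix(runif(96 * 96), 96, 96)
  scores <- vapply(c(0, 1, 2, 4), function(s) {
    brenner_score(gaussian_blur(tex, s))
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("autofocus recovers the textured plane and breaks ties to |z|", {
  cfg <- optical_config(0.785, 0.37, core_diameter_um = 25.6,
                        pixel_size_um = 0.4, grid_shape = c(64, 64))
  vol <- focus_test_volume(40, z_um = seq(0, 60, 20), seed = 5)
  af <- autofocus(cfg, vol, c(0, 20, 40, 60))
  expect_equal(af$z_best, 40)
  # identical images at all planes -> smallest |z|
  flat <- phantom(array(0.5, c(16, 16, 3)), 0.4,
                  z_um = c(-20, 0, 20))
  af2 <- autofocus(cfg, flat, c(-20, 0, 20))
  expect_equal(af2$z_best, 0)
  af3 <- autofocus(cfg, flat, 20)
  expect_equal(af3$z_best, 20)
  expect_error(autofocus(cfg, flat, numeric(0)), "candidate")
  expect_error(acquire_at_plane(cfg, flat, 99), "outside")
})

test_that("puncture series: monotone GLCM contrast, determinism, length", {
  cfg <- optical_config(0.785, 0.37, core_diameter_um = 25.6,
                        pixel_size_um = 0.4, grid_shape = c(64, 64))
  for (s in 1:3) {
    pv <- puncture_volume(seed = s)
    ps <- puncture_series(cfg, pv, c(0, 40, 80),
                          focus_offsets_um = c(-10, 0, 10))
    g <- vapply(ps$records, function(r) {
      glcm_features(r$image)[["contrast"]]
    }, numeric(1))
    expect_true(all(diff(g) < 0))
  }
  pv <- puncture_volume(seed = 1)
  ps1 <- puncture_series(cfg, pv, 40)
  expect_length(ps1$records, 1)
  psa <- puncture_series(cfg, pv, c(0, 40), seed = 3)
  psb <- puncture_series(cfg, pv, c(0, 40), seed = 3)
  expect_identical(psa$records[[2]]$image$pixels,
                   psb$records[[2]]$image$pixels)
  expect_error(puncture_series(cfg, pv, c(0, 400)), "range")
  expect_error(puncture_series(cfg, pv, c(40, 40)), "increasing")
})

test_that("ideal PSF first zero sits at 0.61 lambda/NA within 2%", {
  cfg <- optical_config(0.785, 0.37, core_diameter_um = 40)
  psf <- airy_psf(cfg, shape = c(1, 4001), pixel_size_um = 0.001)
  prof <- psf[1, 2001:4001]
  i_min <- which(diff(prof) > 0)[1]      # first rising point after the peak
  r_zero <- (i_min - 1) * 0.001
  expect_lt(abs(r_zero / (0.61 * 0.785 / 0.37) - 1), 0.02)
})
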