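# Transmission matrix, phase-conjugate focusing, Lee encoding, off-axis
# calibration, angular-spectrum propagation.

test_that("generate_tm is seed-deterministic and column-normalized", {
  cfg <- small_config()
  t1 <- generate_tm(cfg, 32, seed = 7)
  t2 <- generate_tm(cfg, 32, seed = 7)
  expect_identical(t1$entries, t2$entries)
  expect_false(identical(t1$entries, generate_tm(cfg, 32, seed = 8)$entries))
  # unit second moment per column (energy-conservation convention)
  expect_equal(unname(colMeans(Mod(t1$entries)^2)), rep(1, 32))
  t3 <- generate_tm(cfg, 1, seed = 1)
  expect_equal(mean(Mod(t3$entries)^2), 1)
  expect_error(generate_tm(cfg, 0), "positive")
})

test_that("mode count helper matches the V-number arithmetic", {
  cfg <- optical_config(0.785, 0.37, core_diameter_um = 125)
  oracle <- (pi * 125 * 0.37 / 0.785)^2 / 2   # independent arithmetic
  expect_equal(mode_count_estimate(cfg), oracle)
})

test_that("config invariants are enforced", {
  expect_error(optical_config(na = 1.2), "na")
  expect_error(optical_config(0.785, 0.37, 125, pixel_size_um = 2),
               "Nyquist")
  expect_error(optical_config(-1, 0.37, 125), "wavelength")
})

test_that("focus_mask is phase conjugation with the stated enhancement", {
  cfg <- small_config()
  tm <- generate_tm(cfg, 64, seed = 3)
  mk <- focus_mask(tm, c(8, 8))
  tp <- (8 - 1) * 16 + 8
  expect_equal(mk$phases, (-Arg(tm$entries[tp, ])) %% (2 * pi))
  # single mode: enhancement exactly 1
  t1 <- generate_tm(cfg, 1, seed = 5)
  expect_equal(focus_enhancement(t1, c(8, 8))$enhancement, 1)
  # global phase shift leaves the intensity pattern unchanged
  i0 <- apply_mask(tm, mk)
  i1 <- apply_mask(tm, (mk$phases + 1.234) %% (2 * pi))
  expect_equal(i0, i1, tolerance = 1e-12)
  # target outside the core aperture
  expect_error(focus_mask(tm, c(1, 1)), "aperture")
})

test_that("phase-only enhancement follows 1 + (pi/4)(N-1)", {
  cfg <- small_config(grid = c(8, 8))
  for (n_modes in c(64, 256)) {
    etas <- vapply(1:60, function(s) {
      focus_enhancement(generate_tm(cfg, n_modes, seed = s),
                        c(4, 4))$enhancement
    }, numeric(1))
    expect_lt(abs(mean(etas) / enhancement_theory(n_modes) - 1), 0.05)
  }
})

test_that("Lee encoding: carrier-only pattern and shift property", {
  h0 <- lee_encode(matrix(0, 64, 64), 8)
  expect_true(all(h0$pattern %in% c(0L, 1L)))
  expect_equal(mean(h0$pattern), 0.5)    # duty cycle exactly 1/2
  # constant phase 2*pi*k/T shifts the fringes by exactly k pixels
  hs <- lee_encode(matrix(2 * pi * 2 / 8, 64, 64), 8)
  shifted <- h0$pattern[, c(3:64, 1:2)]
  expect_equal(hs$pattern, shifted)
  expect_error(lee_encode(matrix(0, 8, 8), 3), "alias")
})

test_that("Lee round trip recovers smooth masks within 0.1 rad RMS", {
  for (s in 1:3) {
    ph <- make_smooth_phase(256, 20, 1, seed = s)
    dec <- lee_decode(lee_encode(ph, 17))
    expect_lt(phase_rms_error(dec, ph), 0.1)
  }
})

test_that("linear phase ramp decodes to a ramp", {
  n <- 128
  ramp <- matrix(2 * pi * (seq_len(n) - 1) / 256, n, n, byrow = TRUE)
  dec <- lee_decode(lee_encode(ramp, 17))
  expect_lt(phase_rms_error(dec, ramp), 0.1)
})

test_that("off-axis calibration is exact in the noiseless limit", {
  cfg <- small_config()
  tm <- generate_tm(cfg, 32, seed = 11)
  est <- simulate_offaxis_calibration(tm, noise_sd = 0)
  expect_gt(est$fidelity, 0.99)
  # global phase fixed: first entry real-positive
  expect_gt(Re(est$entries[1, 1]), 0)
  expect_lt(abs(Im(est$entries[1, 1])), 1e-9 * Mod(est$entries[1, 1]))
})

test_that("focusing through the estimated TM retains >= 90% enhancement", {
  cfg <- small_config()
  tm <- generate_tm(cfg, 64, seed = 2)
  est <- simulate_offaxis_calibration(tm, noise_sd = 0)
  fe_true <- focus_enhancement(tm, c(8, 8))
  i_est <- apply_mask(tm, focus_mask(est, c(8, 8)))
  eta_est <- i_est[8, 8] / fe_true$background
  expect_gte(eta_est / fe_true$enhancement, 0.9)
})

test_that("calibration degrades monotonically with noise and rejects a
           degenerate reference", {
  cfg <- small_config()
  tm <- generate_tm(cfg, 16, seed = 4)
  fids <- vapply(c(0, 0.05, 0.5), function(ns) {
    simulate_offaxis_calibration(tm, noise_sd = ns, seed = 9)$fidelity
  }, numeric(1))
  expect_true(all(diff(fids) < 0))
  expect_error(simulate_offaxis_calibration(tm, ref_amplitude = 0),
               "demodulation error")
  expect_error(simulate_offaxis_calibration(tm, tilt_frac = 0.05),
               "sideband")
})

test_that("calibration works for a non-one-hot spanning basis", {
  cfg <- small_config()
  tm <- generate_tm(cfg, 16, seed = 6)
  set.seed(1)
  b <- matrix(sample(c(-1, 1), 256, TRUE), 16, 16) + 0i
  est <- simulate_offaxis_calibration(tm, basis = b, noise_sd = 0)
  expect_gt(est$fidelity, 0.99)
})

test_that("angular-spectrum propagation: identity, invertibility, energy", {
  cfg <- optical_config(0.785, 0.37, 40, pixel_size_um = 1,
                        grid_shape = c(32, 32))
  set.seed(3)
  f <- matrix(complex(real = rnorm(1024), imaginary = rnorm(1024)), 32, 32)
  expect_equal(propagate_angular_spectrum(f, 0, cfg), f + 0i)
  # band-limit once, then propagation must be exactly invertible
  fb <- propagate_angular_spectrum(f, 1e-9, cfg)
  fwd <- propagate_angular_spectrum(fb, 37.3, cfg)
  back <- propagate_angular_spectrum(fwd, -37.3, cfg)
  expect_lt(max(Mod(back - fb)), 1e-6 * max(Mod(fb)))
  expect_equal(sum(Mod(fwd)^2), sum(Mod(fb)^2),
               tolerance = 1e-6)
})

test_that("Gaussian beam expands per the analytic w(z)", {
  lam <- 0.785
  w0 <- 3
  zr <- pi * w0^2 / lam
  cfg <- optical_config(lam, 0.37, 80, pixel_size_um = 0.4,
                        grid_shape = c(192, 192))
  px <- 0.4
  cy <- (192 + 1) / 2
  r2 <- outer(((seq_len(192) - cy) * px)^2, ((seq_len(192) - cy) * px)^2, "+")
  field <- exp(-r2 / w0^2)
  for (z in c(20, 36)) {
    out <- propagate_angular_spectrum(field, z, cfg)
    i2 <- Mod(out)^2
    w_meas <- sqrt(2 * sum(i2 * r2) / sum(i2))
    w_true <- w0 * sqrt(1 + (z / zr)^2)
    expect_lt(abs(w_meas / w_true - 1), 0.01)
  }
})

test_that("3-D TM plane composition matches direct propagation", {
  cfg <- small_config()
  tm <- generate_tm(cfg, 4, seed = 8, z_planes = c(10, 20))
  tmz <- tm_at_plane(tm, 10)
  col1 <- propagate_angular_spectrum(matrix(tm$entries[, 1], 16, 16), 10, cfg)
  expect_equal(tmz$entries[, 1], as.vector(col1))
  expect_error(generate_tm(cfg, 4, z_planes = c(20, 10)), "increasing")
})
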