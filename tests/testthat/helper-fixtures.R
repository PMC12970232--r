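# Shared fixtures, all generated in code.

# periodic smooth random phase field (unit-free), safe for FFT round trips
make_smooth_phase <- function(n, sigma_px, amp, seed) {
  set.seed(seed)
  f <- stats::fft(matrix(stats::rnorm(n * n), n, n))
  fr <- c(0:(n / 2 - 1), -(n / 2):-1) / n
  h <- exp(-2 * pi^2 * sigma_px^2 * outer(fr^2, fr^2, "+"))
  ph <- Re(stats::fft(f * h, inverse = TRUE) / n^2)
  ph / stats::sd(ph) * amp
}

# small optical configuration used across fiber tests
small_config <- function(grid = c(16, 16), pixel = 1) {
  optical_config(0.785, 0.37, core_diameter_um = grid[1] * pixel * 2.5,
                 pixel_size_um = pixel, grid_shape = grid)
}

# memoized small labeled cohort (direct mode) for pipeline smoke tests
.fixture_env <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- cohort(12, image_size = c(128, 128), seed = 301L)
  }
  .fixture_env$cohort
}
small_metric_table <- function() {
  if (is.null(.fixture_env$mtab)) {
    .fixture_env$mtab <- feature_table(small_cohort())
  }
  .fixture_env$mtab
}
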