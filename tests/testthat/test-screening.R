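grid <- seq(0.4, 2.0, by = 0.001)

test_that("baseline follows peak-free profiles and bridges narrow peaks", {
  # smooth monotone decay: baseline deviates by < 1%
  y <- 1e4 * grid^(-2) + 50
  p <- pattern1d(grid, y, sqrt(y))
  b <- estimate_baseline(p, half_window = 40)
  expect_lt(max(abs(b - y) / y), 0.01)
  expect_true(all(b <= y + 1e-9))

  # constant profile: baseline is that constant
  pc <- pattern1d(grid, rep(77, length(grid)), rep(1, length(grid)))
  expect_equal(estimate_baseline(pc, 40), rep(77, length(grid)))

  # decay + one narrow peak: the peak area is recovered on subtraction
  area_true <- 300
  peak <- area_true * pseudo_voigt(grid - 1.2, 0.02, 0)
  p2 <- pattern1d(grid, y + peak, sqrt(y))
  b2 <- estimate_baseline(p2, half_window = 40)
  area_rec <- sum((p2$intensity - b2)[abs(grid - 1.2) < 0.1]) * 0.001
  expect_equal(area_rec, area_true, tolerance = 0.05)
  expect_error(estimate_baseline(p, half_window = 1), "at least 2")
  expect_error(estimate_baseline(pattern1d(1:5, 1:5, rep(1, 5)), 10), "shorter")
})

test_that("peak detection finds constructed peaks and rejects pure noise", {
  # false-positive rate on pure noise at k_sigma = 5
  empty <- 0
  for (seed in 1:100) {
    p <- make_peak_profile(grid, numeric(0), numeric(0), noise_sd = 3,
                           seed = seed)
    if (nrow(detect_peaks(p, k_sigma = 5)) == 0) empty <- empty + 1
  }
  expect_gte(empty, 95)

  # one peak of SNR 20: exactly one call within a grid step of the centre
  p1 <- make_peak_profile(grid, 1.1, 20 * 3, noise_sd = 3, seed = 7)
  calls <- detect_peaks(p1, k_sigma = 5)
  expect_equal(nrow(calls), 1)
  expect_lt(abs(calls$position - 1.1), 0.005)
  expect_gt(calls$snr, 10)

  # two peaks separated by >= 3 FWHM give two calls
  p2 <- make_peak_profile(grid, c(0.9, 1.5), c(60, 75), noise_sd = 3, seed = 8)
  expect_equal(nrow(detect_peaks(p2, k_sigma = 5)), 2)
})

test_that("peak positions on simulated patterns match the reflection list", {
  # well-separated cubic reflections, strong intensities, known sigma
  cell <- unit_cell("cubic", 100)
  # Gaussian shape: Lorentzian tails of touching strong peaks would fuse
  # adjacent threshold runs, which is a property of the data, not the caller
  m <- pawley_model(cell, space_group("P-cubic"), 1.24, c(0.4, 2.0),
                    profile = profile_params(eta = 0, W = 2.5e-4))
  m$reflections$intensity <- rep(50, nrow(m$reflections))
  p <- simulate_profile(m, grid)
  obs <- pattern1d(grid, p$intensity + 100, rep(1, length(grid)))
  calls <- detect_peaks(obs, k_sigma = 5, noise = "sigma", half_window = 60)
  strong <- calls[calls$snr >= 10, ]
  expect_equal(nrow(strong), nrow(m$reflections))
  for (i in seq_len(nrow(strong))) {
    expect_lt(min(abs(strong$position[i] - m$reflections$two_theta)), 0.004)
  }
})

test_that("crystal-content calls separate phases from mock samples", {
  cfg <- experiment_config(seed = 88)
  mock <- simulate_profile_pair(phantom_preset("mock"), cfg)
  d_mock <- subtract_buffer(mock$sample, mock$buffer)
  expect_false(classify_crystal_content(d_mock)$crystal_present)

  hex <- simulate_profile_pair(phantom_preset("hex1"), cfg)
  res <- classify_crystal_content(subtract_buffer(hex$sample, hex$buffer))
  expect_true(res$crystal_present)
  # the same Bragg signal diluted 64-fold sinks below the noise floor
  weak <- phantom_preset("hex1", crystal_cell_fraction = 1 / 64)
  hex64 <- simulate_profile_pair(weak, cfg)
  res64 <- classify_crystal_content(subtract_buffer(hex64$sample, hex64$buffer))
  expect_false(res64$crystal_present)
  expect_gt(res$score, res64$score)
})

test_that("specificity: mock-like profiles stay below 5% false positives", {
  fp <- 0
  n_rep <- 200
  short_grid <- seq(0.4, 2.0, by = 0.002)
  for (seed in seq_len(n_rep)) {
    pair <- simulate_profile_pair(phantom_preset("mock"),
                                  experiment_config(seed = 5000 + seed),
                                  grid = short_grid)
    d <- subtract_buffer(pair$sample, pair$buffer)
    if (classify_crystal_content(d)$crystal_present) fp <- fp + 1
  }
  expect_lte(fp / n_rep, 0.05)
})

test_that("screening results tidy into peak tables and one-row summaries", {
  p <- make_peak_profile(grid, c(0.9, 1.5), c(90, 120), noise_sd = 3, seed = 4)
  res <- classify_crystal_content(p)
  expect_true(res$crystal_present)
  td <- tidy(res)
  expect_true(all(td$crystal_present))
  gl <- glance(res)
  expect_equal(gl$n_significant, 2)
  expect_equal(gl$k_sigma, 5)
})
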