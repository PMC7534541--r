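test_that("irradiated volume reproduces the beam-times-capillary arithmetic", {
  expect_equal(irradiated_volume(0.20, 0.12, 1.8), 0.0432)
  expect_equal(irradiated_volume(0.20, 0.12, 1.8, digits = 3), 0.043)
  expect_equal(irradiated_volume(1, 1, 1), 1)
  expect_equal(irradiated_volume(2 * 0.2, 0.12, 1.8), 2 * 0.0432)  # trilinear
})

test_that("acquisition time reflects the frame scheme", {
  expect_equal(acquisition_time(experiment_config()), 4)   # 80 x 0.05 s
  one <- experiment_config(n_sample_frames = 1, n_buffer_frames = 1,
                           frame_exposure = 0.045, readout = 1e-12)
  expect_equal(acquisition_time(one), 2 * 0.045, tolerance = 1e-9)
  dbl <- experiment_config(n_sample_frames = 80, n_buffer_frames = 80)
  expect_equal(acquisition_time(dbl), 8)
  expect_error(experiment_config(frame_exposure = -1), "positive")
})

test_that("profile pairs are reproducible and mean-faithful", {
  ph <- phantom_preset("catb")
  cfg <- experiment_config(seed = 12)
  a <- simulate_profile_pair(ph, cfg)
  b <- simulate_profile_pair(ph, cfg)
  expect_identical(a$sample$intensity, b$sample$intensity)
  expect_identical(a$buffer$intensity, b$buffer$intensity)
  c2 <- simulate_profile_pair(ph, experiment_config(seed = 13))
  expect_false(identical(a$sample$intensity, c2$sample$intensity))

  # Monte-Carlo mean of (sample - buffer) matches the noise-free Bragg part
  grid <- seq(0.4, 2.0, by = 0.002)
  diffs <- sapply(1:40, function(s) {
    pair <- simulate_profile_pair(ph, experiment_config(seed = 9000 + s), grid)
    pair$sample$intensity - pair$buffer$intensity
  })
  bragg <- simulate_profile_pair(ph, cfg, grid)$mean_bragg
  mc_mean <- rowMeans(diffs)
  mc_se <- apply(diffs, 1, sd) / sqrt(ncol(diffs))
  expect_lt(mean(abs(mc_mean - bragg) > 3 * mc_se), 0.02)
})

test_that("a crystal-free phantom yields no significant peaks", {
  hits <- 0
  for (s in 1:20) {
    pair <- simulate_profile_pair(phantom_preset("mock"),
                                  experiment_config(seed = 400 + s),
                                  grid = seq(0.4, 2.0, by = 0.002))
    d <- subtract_buffer(pair$sample, pair$buffer)
    if (nrow(detect_peaks(d, k_sigma = 5)) > 0) hits <- hits + 1
  }
  expect_lte(hits, 1)   # >= 95% of seeds clean
})

test_that("strong phantoms are detected at the predicted angles", {
  pair <- simulate_profile_pair(phantom_preset("hex1"),
                                experiment_config(seed = 3))
  d <- subtract_buffer(pair$sample, pair$buffer)
  calls <- detect_peaks(d, k_sigma = 5)
  refl <- generate_reflections(unit_cell("hexagonal", 58.01, c = 195.2),
                               space_group("P6522"), c(0.3, 2.2), 1.24)
  strong <- calls[calls$snr >= 10, ]
  expect_gt(nrow(strong), 0)
  for (i in seq_len(nrow(strong))) {
    expect_lt(min(abs(strong$position[i] - refl$two_theta)), 0.01)
  }
})

test_that("dilution series halve the crystal fraction with shared fingerprint", {
  ph <- phantom_preset("catb", crystal_cell_fraction = 0.9)
  series <- make_dilution_series(ph, experiment_config(seed = 21), n_steps = 4,
                                 grid = seq(0.4, 2.0, by = 0.002))
  expect_equal(nrow(series$steps), 5)
  expect_equal(series$steps$fraction,
               c(0.9, 0.45, 0.225, 0.1125, 0.05625))
  expect_equal(series$steps$dilution_factor, c(1, 2, 4, 8, 16))
  # Bragg area scales linearly with the fraction (noise-free expectation)
  areas <- vapply(0:4, function(j) {
    phj <- ph; phj$crystal_cell_fraction <- 0.9 / 2^j
    sum(simulate_profile_pair(phj, experiment_config(seed = 1),
                              seq(0.4, 2.0, by = 0.002))$mean_bragg)
  }, numeric(1))
  expect_equal(areas / areas[1], 1 / 2^(0:4), tolerance = 1e-9)
})

test_that("detector series produce granular rings at lattice angles", {
  geom <- detector_geometry(distance = 3000, pixel_size = 0.75,
                            beam_center = c(160.5, 160.5), wavelength = 1.24,
                            n_rows = 320, n_cols = 320)
  cfg <- experiment_config(seed = 6)
  # analysis window past the steep low-angle background
  rng <- c(0.3, 2.2)
  # no crystallites: integration of the summed frames shows no peaks
  ph0 <- phantom_preset("hex1", n_crystallites = 0)
  ser0 <- suppressMessages(simulate_detector_series(ph0, cfg, geom))
  expect_length(ser0$sample_frames, 40)
  p0 <- azimuthal_integrate(sum_frames(ser0$sample_frames), geom, n_bins = 150,
                            two_theta_range = rng)
  b0 <- azimuthal_integrate(sum_frames(ser0$buffer_frames), geom, n_bins = 150,
                            two_theta_range = rng)
  expect_equal(nrow(detect_peaks(subtract_buffer(p0, b0), k_sigma = 5,
                                 half_window = 15)), 0)

  # rings fall at the radii the lattice predicts
  ph1 <- phantom_preset("hex1", n_crystallites = 800)
  ser1 <- suppressMessages(simulate_detector_series(ph1, cfg, geom,
                                                    rocking_fraction = 0.02,
                                                    spot_counts = 8000))
  p1 <- azimuthal_integrate(sum_frames(ser1$sample_frames), geom, n_bins = 150,
                            two_theta_range = rng)
  b1 <- azimuthal_integrate(sum_frames(ser1$buffer_frames), geom, n_bins = 150,
                            two_theta_range = rng)
  calls <- detect_peaks(subtract_buffer(p1, b1), k_sigma = 5, half_window = 15)
  expect_gt(nrow(calls), 1)
  for (i in seq_len(nrow(calls))) {
    expect_lt(min(abs(calls$position[i] - ser1$reflections$two_theta)), 0.03)
  }
})

test_that("ring granularity decreases with the crystallite count", {
  geom <- detector_geometry(distance = 3000, pixel_size = 0.75,
                            beam_center = c(96.5, 96.5), wavelength = 1.24,
                            n_rows = 192, n_cols = 192)
  ring_cv <- function(n_cryst, seed) {
    # Luc-like cell: its low-angle rings sit well inside this detector
    ph <- phantom_preset("luc", n_crystallites = n_cryst,
                         background = c(A = 0.05, p = 3, C = 1))
    ser <- suppressMessages(simulate_detector_series(
      ph, experiment_config(seed = seed), geom, rocking_fraction = 0.05,
      spot_counts = 4000 / n_cryst * 100))
    total <- sum_frames(ser$sample_frames)$counts
    ridx <- which(ser$reflections$two_theta < 1.1)[1]
    r_px <- 3000 * tan(ser$reflections$two_theta[ridx] * pi / 180) / 0.75
    phis <- seq(0, 2 * pi, length.out = 181)[-181]
    vals <- vapply(phis, function(a) {
      i <- round(96.5 + r_px * cos(a)); j <- round(96.5 + r_px * sin(a))
      mean(total[(i - 1):(i + 1), (j - 1):(j + 1)])
    }, numeric(1))
    sd(vals) / mean(vals)
  }
  cvs <- vapply(c(10, 100, 1000), function(n) {
    mean(vapply(1:3, function(s) ring_cv(n, 50 + s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(cvs) < 0))
})
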