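# Shared noise-free reference model: CatB-like phase over the fingerprint
# window, 12-term background, known intensities.
make_truth <- function() {
  cell <- unit_cell("tetragonal", 125.69, c = 54.408)
  m <- pawley_model(cell, space_group("P42212"), 1.24, c(0.4, 2.0),
                    zero_shift = 0.004,
                    profile = profile_params(eta = 0.4, W = 2.5e-4),
                    background = background_model(c(300, -80, 25, -6, 2, 1),
                                                  c(0.4, 2.0)))
  set.seed(17)
  m$reflections$intensity <- rlnorm(nrow(m$reflections), 3, 0.5)
  m
}

test_that("fit statistics follow the weighted-residual definitions", {
  s <- fit_statistics(c(1, 2), c(1, 1), c(1, 1), 0)
  expect_equal(s$rwp, 100 * sqrt(1 / 5))
  expect_equal(s$chi2_red, 0.5)
  y <- c(3, 1, 4, 1, 5)
  expect_equal(fit_statistics(y, y, rep(2, 5), 1)$rwp, 0)
  expect_equal(fit_statistics(y, y, rep(2, 5), 1)$chi2_red, 0)
  # Rwp is scale invariant
  yc <- y + c(0.1, -0.2, 0, 0.3, -0.1)
  w <- c(1, 2, 3, 4, 5)
  expect_equal(fit_statistics(10 * y, 10 * yc, w, 2)$rwp,
               fit_statistics(y, yc, w, 2)$rwp)
  # with 1/sigma^2 weights the GoF convention coincides with reduced chi2
  expect_equal(fit_statistics(y, yc, w, 2)$gof,
               fit_statistics(y, yc, w, 2)$chi2_red)
  expect_error(fit_statistics(y, yc, w, 5), "more data points")
})

test_that("equipartition splits overlapping groups equally", {
  prof <- profile_params(W = 4e-4)  # FWHM 0.02 deg
  grid <- seq(0.4, 2.0, by = 0.001)
  # three exactly coincident unresolvable reflections of total area 300
  refl <- tibble::tibble(h = 1:3, k = 0L, l = 0L, d = 1,
                         two_theta = rep(1.2, 3), s = 1,
                         multiplicity = rep(1L, 3))
  y <- 50 + 300 * pseudo_voigt(grid - 1.2, 0.02, 0)
  obs <- pattern1d(grid, y, sqrt(pmax(y, 1)))
  ints <- equipartition_init(refl, prof, obs)
  expect_equal(ints, rep(100, 3), tolerance = 0.1)

  # well-separated peaks each get their own local area
  refl2 <- tibble::tibble(h = 1:2, k = 0L, l = 0L, d = 1,
                          two_theta = c(0.8, 1.6), s = 1,
                          multiplicity = c(1L, 1L))
  y2 <- 50 + 200 * pseudo_voigt(grid - 0.8, 0.02, 0) +
    80 * pseudo_voigt(grid - 1.6, 0.02, 0)
  ints2 <- equipartition_init(refl2, prof, pattern1d(grid, y2, sqrt(y2)))
  expect_equal(ints2, c(200, 80), tolerance = 0.15)
})

test_that("overlap grouping matches a brute-force chaining oracle", {
  set.seed(5)
  for (rep in 1:20) {
    pos <- sort(runif(15, 0.4, 2.0))
    radius <- runif(1, 0.005, 0.2)
    grp <- xrpdscreen:::overlap_groups(pos, radius)
    # oracle: transitive closure of the pairwise |di - dj| <= radius relation
    n <- length(pos)
    adj <- abs(outer(pos, pos, `-`)) <= radius
    reach <- adj
    for (k in seq_len(n)) reach <- reach | (reach %*% reach > 0)
    oracle <- match(apply(reach, 1, function(r) min(which(r))),
                    unique(apply(reach, 1, function(r) min(which(r)))))
    expect_equal(as.integer(factor(grp)), oracle)
  }
})

test_that("refinement of a noise-free profile from truth is a fixed point", {
  truth <- make_truth()
  grid <- seq(0.41, 1.99, by = 0.001)
  obs <- simulate_profile(truth, grid)
  start <- truth
  fit <- pawley_refine(obs, start,
                       pawley_config(scan_scale = FALSE, profile_free = character()))
  expect_lt(fit$rwp, 1e-6)
  expect_equal(fit$model$cell$a, 125.69, tolerance = 1e-7)
  expect_equal(fit$model$cell$c, 54.408, tolerance = 1e-7)
  expect_equal(fit$model$zero_shift, 0.004, tolerance = 1e-6)
})

test_that("with frozen positions the Pawley intensities are the exact WLS solution", {
  truth <- make_truth()
  grid <- seq(0.41, 1.99, by = 0.001)
  set.seed(23)
  mu <- simulate_profile(truth, grid)$intensity
  yobs <- rpois(length(grid), mu)
  obs <- pattern1d(grid, yobs, sqrt(pmax(yobs, 1)))
  fit <- pawley_refine(obs, truth,
                       pawley_config(refine_zero = FALSE, refine_cell = FALSE,
                                     scan_scale = FALSE,
                                     profile_free = character()))
  # closed-form weighted LS on the same design
  Xb <- xrpdscreen:::.cheb_design((2 * grid - sum(c(0.4, 2))) / 1.6,
                                  length(truth$background$coeffs))
  Xp <- xrpdscreen:::.peak_design(grid, truth$reflections, truth$zero_shift,
                                  truth$profile)
  sw <- 1 / obs$sigma
  beta <- qr.coef(qr(cbind(Xb, Xp) * sw), yobs * sw)
  expect_true(all(beta[-seq_len(ncol(Xb))] > 0))  # interior solution
  expect_equal(fit$model$reflections$intensity,
               unname(beta[-seq_len(ncol(Xb))]), tolerance = 1e-8)
  expect_equal(fit$model$background$coeffs, unname(beta[seq_len(ncol(Xb))]),
               tolerance = 1e-8)
})

test_that("cell parameters are recovered from perturbed starts on noisy data", {
  # one seed per phase here; the 20-seed median protocol backs the
  # acceptance checks
  ph <- phantom_preset("catb", zero_shift = 0.003)
  pair <- simulate_profile_pair(ph, experiment_config(seed = 301))
  fit <- run_refine(pair$sample,
                    unit_cell("tetragonal", 125.69 * 1.02, c = 54.408 * 1.02),
                    "P42212", window = c(0.4, 2.0))
  expect_true(fit$converged)
  expect_lt(abs(fit$model$cell$a - 125.69) / 125.69, 5e-4)
  expect_lt(abs(fit$model$cell$c - 54.408) / 54.408, 5e-4)
  expect_lt(abs(fit$model$zero_shift - 0.003), 0.005)

  ph2 <- phantom_preset("hex1")
  pair2 <- simulate_profile_pair(ph2, experiment_config(seed = 302),
                                 grid = seq(0.3, 3.2, by = 0.001))
  fit2 <- run_refine(pair2$sample,
                     unit_cell("hexagonal", 58.01 * 0.98, c = 195.2 * 0.98),
                     "P6522", window = c(0.4, 3.0))
  expect_lt(abs(fit2$model$cell$a - 58.01) / 58.01, 5e-4)
  expect_lt(abs(fit2$model$cell$c - 195.2) / 195.2, 5e-4)

  # accepted steps never increase the weighted residual
  expect_true(all(diff(fit$history) <= 1e-8 * fit$history[-length(fit$history)]))
  # identifiability: all parameter esds are finite on well-posed data
  expect_true(all(is.finite(fit$esds)))
  # esds should bracket the actual cell error within an order of magnitude
  expect_lt(abs(fit$model$cell$a - 125.69), 50 * fit$esds[["a"]] + 0.05)
})

test_that("degenerate designs are reported with the offending parameters", {
  truth <- make_truth()
  grid <- seq(0.41, 1.99, by = 0.001)
  obs <- simulate_profile(truth, grid)
  start <- truth
  # duplicate a reflection row: two identical design columns
  start$reflections <- start$reflections[c(1, seq_len(nrow(start$reflections))), ]
  expect_error(
    pawley_refine(obs, start, pawley_config(scan_scale = FALSE,
                                            profile_free = character())),
    "degenerate")
})

test_that("tidy, glance and reports expose the refined parameters", {
  truth <- make_truth()
  grid <- seq(0.41, 1.99, by = 0.001)
  obs <- simulate_profile(truth, grid)
  fit <- pawley_refine(obs, truth, pawley_config(scan_scale = FALSE,
                                                 profile_free = character()))
  td <- tidy(fit)
  expect_true(all(c("a", "c", "zero") %in% td$term))
  expect_true(any(td$type == "intensity"))
  gl <- glance(fit)
  expect_equal(gl$n_points, length(grid))
  expect_true(gl$converged)

  prefix <- file.path(withr::local_tempdir(), "catbfit")
  write_pawley_report(fit, prefix)
  rep <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(rep$cell$a, fit$model$cell$a, tolerance = 1e-9)
  expect_equal(rep$space_group, "P42212")
  prof <- read.table(paste0(prefix, "_profile.dat"))
  expect_equal(ncol(prof), 5)        # axis, obs, calc, diff, background
  expect_equal(nrow(prof), length(grid))
  expect_equal(prof[[2]] - prof[[3]], prof[[4]], tolerance = 1e-9)
})
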