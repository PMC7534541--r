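#' Experiment configuration of the screening beamline setup
#'
#' Defaults reproduce the published data-collection scheme: 10 keV photons
#' (1.24 A), 3.00 m sample–detector distance, a 0.20 x 0.12 mm beam through a
#' 1.8 mm quartz capillary, and 40 sample frames separated by 40 buffer
#' frames of 0.045 s exposure + 0.005 s readout each (4 s total per data
#' set).
#'
#' @param wavelength Wavelength in Angstrom.
#' @param distance Sample–detector distance in mm.
#' @param beam_w,beam_h Beam width/height (FWHM) in mm.
#' @param capillary_path Capillary path length in mm.
#' @param n_sample_frames,n_buffer_frames Frames per sample / buffer series.
#' @param frame_exposure,readout Per-frame exposure and readout in seconds.
#' @param seed Integer seed for all randomness derived from this config.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(wavelength = 1.24, distance = 3000,
                              beam_w = 0.20, beam_h = 0.12,
                              capillary_path = 1.8,
                              n_sample_frames = 40, n_buffer_frames = 40,
                              frame_exposure = 0.045, readout = 0.005,
                              seed = 1L) {
  vals <- c(wavelength, distance, beam_w, beam_h, capillary_path,
            n_sample_frames, n_buffer_frames, frame_exposure, readout)
  if (any(vals <= 0)) stop("all configuration values must be positive", call. = FALSE)
  structure(list(wavelength = wavelength, distance = distance,
                 beam_w = beam_w, beam_h = beam_h,
                 capillary_path = capillary_path,
                 n_sample_frames = as.integer(n_sample_frames),
                 n_buffer_frames = as.integer(n_buffer_frames),
                 frame_exposure = frame_exposure, readout = readout,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Irradiated sample volume
#'
#' Rectangular-beam approximation: beam width x beam height x capillary path.
#' With the default 0.20 x 0.12 mm beam and 1.8 mm capillary this is
#' 0.0432 mm^3 (0.043 mm^3 at the printed precision) — the volume that sets
#' how many cells contribute scattering.
#'
#' @param beam_w,beam_h Beam dimensions in mm.
#' @param path Capillary path length in mm.
#' @param digits Optional rounding of the returned value.
#' @return Volume in mm^3.
#' @export
irradiated_volume <- function(beam_w = 0.20, beam_h = 0.12, path = 1.8,
                              digits = NULL) {
  stopifnot(beam_w > 0, beam_h > 0, path > 0)
  v <- beam_w * beam_h * path
  if (!is.null(digits)) v <- round(v, digits) else v
}

#' Total acquisition time per data set
#'
#' `(n_sample_frames + n_buffer_frames) * (frame_exposure + readout)`;
#' 80 x 0.05 s = 4 s at the defaults.
#'
#' @param cfg An [experiment_config()].
#' @return Seconds.
#' @export
acquisition_time <- function(cfg = experiment_config()) {
  stopifnot(inherits(cfg, "experiment_config"))
  (cfg$n_sample_frames + cfg$n_buffer_frames) * (cfg$frame_exposure + cfg$readout)
}

#' Phantom: a synthetic crystal-containing cell sample
#'
#' Describes the generative model of one sample: the crystalline phase (unit
#' cell + space group), the fraction of cells containing crystals (which
#' scales the Bragg intensities linearly, mirroring a 1:2 dilution with mock
#' cells), a finite crystallite count (granularity of the simulated
#' Debye–Scherrer rings), per-reflection mean intensities (seeded log-normal
#' draws — Pawley treats them as free, so no structure factors are
#' computed), and a smooth Porod-like cellular background
#' \eqn{I_{bg}(s) = A s^{-p} + C}.
#'
#' @param cell A [unit_cell()].
#' @param rules A [space_group()].
#' @param crystal_cell_fraction Fraction of cells containing crystals, 0..1.
#' @param n_crystallites Crystallites in the irradiated volume (ring
#'   granularity).
#' @param background Named vector `c(A=, p=, C=)` of the background law in
#'   expected counts s^-1 per bin; `p` in `[2, 4]`.
#' @param peak_scale Overall Bragg amplitude scale (expected counts s^-1 per
#'   unit pseudo-Voigt area at full crystal fraction).
#' @param sdlog Log-normal sd of per-reflection mean intensities.
#' @param zero_shift Instrumental zero shift in degrees.
#' @param profile A [profile_params()].
#' @param label Sample label carried into pattern metadata.
#' @param intensity_seed Seed of the per-reflection intensity draws. This is
#'   a property of the phase, not of a measurement: replicate measurements of
#'   the same phantom share the same relative peak intensities and differ
#'   only in counting noise. Defaults to a hash of `label`.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(cell, rules, crystal_cell_fraction = 1,
                         n_crystallites = 500,
                         background = c(A = 50, p = 3, C = 100),
                         peak_scale = 30, sdlog = 1, zero_shift = 0,
                         profile = profile_params(eta = 0.4, U = 0, V = 0,
                                                  W = 2.5e-4),
                         label = rules$symbol, intensity_seed = NULL) {
  stopifnot(inherits(cell, "unit_cell"), inherits(rules, "space_group"))
  if (crystal_cell_fraction < 0 || crystal_cell_fraction > 1) {
    stop("crystal_cell_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (background[["p"]] < 2 || background[["p"]] > 4) {
    stop("background power p must lie in [2, 4]", call. = FALSE)
  }
  if (n_crystallites < 0) stop("n_crystallites must be non-negative", call. = FALSE)
  if (is.null(intensity_seed)) {
    intensity_seed <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) * 101L
  }
  structure(list(cell = cell, rules = rules,
                 crystal_cell_fraction = crystal_cell_fraction,
                 n_crystallites = as.integer(n_crystallites),
                 background = background, peak_scale = peak_scale,
                 sdlog = sdlog, zero_shift = zero_shift, profile = profile,
                 label = label, intensity_seed = as.integer(intensity_seed)),
            class = "phantom_spec")
}

#' Built-in phantom presets for the four screened phases
#'
#' Cells and space groups follow the refined values of the four in cellulo
#' crystal phases: Luc-like P41212 (a = b = 129.13, c = 97.1 A), IMPDH-like
#' P4212 (a = b = 209.3, c = 93.44 A), CatB-like P42212 (a = b = 125.69,
#' c = 54.408 A) and HEX-1-like P6522 (a = b = 58.01, c = 195.2 A).
#'
#' @param name One of `"luc"`, `"impdh"`, `"catb"`, `"hex1"`, `"mock"` (no
#'   crystalline phase: fraction 0, CatB-like cell as a placeholder lattice).
#' @param ... Overrides passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
phantom_preset <- function(name = c("luc", "impdh", "catb", "hex1", "mock"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    luc   = list(cell = unit_cell("tetragonal", 129.13, c = 97.1),
                 rules = space_group("P41212")),
    impdh = list(cell = unit_cell("tetragonal", 209.3, c = 93.44),
                 rules = space_group("P4212")),
    catb  = list(cell = unit_cell("tetragonal", 125.69, c = 54.408),
                 rules = space_group("P42212")),
    hex1  = list(cell = unit_cell("hexagonal", 58.01, c = 195.2),
                 rules = space_group("P6522")),
    mock  = list(cell = unit_cell("tetragonal", 125.69, c = 54.408),
                 rules = space_group("P42212"), crystal_cell_fraction = 0)
  )
  args <- utils::modifyList(c(base, list(label = name)), list(...))
  do.call(phantom_spec, args)
}

# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

# deterministic per-reflection mean intensities (log-normal, seeded by the
# phantom itself: the fingerprint is a property of the phase)
.phantom_intensities <- function(phantom, n_refl) {
  .with_seed(phantom$intensity_seed * 7 + 13,
             stats::rlnorm(n_refl, meanlog = 0, sdlog = phantom$sdlog))
}

# noise-free mean model on a 2-theta grid (counts per second per bin)
.phantom_mean_rates <- function(phantom, cfg, grid) {
  s <- s_from_two_theta(grid, cfg$wavelength)
  bg <- phantom$background[["A"]] * s^(-phantom$background[["p"]]) +
    phantom$background[["C"]]
  window <- range(grid) + c(-0.05, 0.05)
  window[1] <- max(window[1], 1e-3)
  model <- pawley_model(phantom$cell, phantom$rules, cfg$wavelength, window,
                        zero_shift = phantom$zero_shift,
                        profile = phantom$profile)
  n_refl <- nrow(model$reflections)
  ints <- .phantom_intensities(phantom, n_refl)
  model$reflections$intensity <- ints
  bragg <- phantom$peak_scale * phantom$crystal_cell_fraction *
    .bragg_component(model, grid)
  list(background = bg, bragg = bragg, model = model)
}

#' Simulate a paired sample/buffer profile measurement
#'
#' The buffer is a Poisson realisation of the smooth cellular/buffer
#' background alone; the sample adds the Bragg component of the phantom's
#' phase scaled by its crystal-cell fraction. Expected counts are the mean
#' model times the accumulated exposure (frames x frame exposure). Sigmas
#' are counting uncertainties \eqn{\sqrt{\max(N, 1)}}. Fully reproducible
#' from `cfg$seed`.
#'
#' @param phantom A [phantom_spec()].
#' @param cfg An [experiment_config()].
#' @param grid Increasing 2-theta values (degrees).
#' @return A list with `sample` and `buffer` `xrd_pattern`s and the
#'   noise-free `mean_bragg` component (counts).
#' @export
simulate_profile_pair <- function(phantom, cfg = experiment_config(),
                                  grid = seq(0.3, 2.2, by = 0.001)) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(cfg, "experiment_config"))
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  rates <- .phantom_mean_rates(phantom, cfg, grid)
  t_sample <- cfg$n_sample_frames * cfg$frame_exposure
  t_buffer <- cfg$n_buffer_frames * cfg$frame_exposure
  mu_sample <- (rates$background + rates$bragg) * t_sample
  mu_buffer <- rates$background * t_buffer
  counts <- .with_seed(cfg$seed * 2 + 1, list(
    sample = stats::rpois(length(grid), mu_sample),
    buffer = stats::rpois(length(grid), mu_buffer)
  ))
  meta <- list(label = phantom$label, fraction = phantom$crystal_cell_fraction,
               exposure = t_sample, wavelength = cfg$wavelength, seed = cfg$seed)
  list(
    sample = pattern1d(grid, counts$sample, sqrt(pmax(counts$sample, 1)),
                       axis_kind = "two_theta_deg", meta = meta),
    buffer = pattern1d(grid, counts$buffer, sqrt(pmax(counts$buffer, 1)),
                       axis_kind = "two_theta_deg",
                       meta = utils::modifyList(meta, list(label = "buffer"))),
    mean_bragg = rates$bragg * t_sample,
    model = rates$model
  )
}

#' Simulate a granular Debye–Scherrer detector frame series
#'
#' Each of the phantom's crystallites contributes Bragg spots on rings of
#' radius \eqn{r_k = D \tan(2\theta_k)} at independent random azimuths: a
#' per-crystallite, per-reflection Bernoulli trial with probability
#' proportional to multiplicity times a rocking fraction decides whether a
#' given crystallite is in diffracting orientation for that ring. The smooth
#' cellular background is added radially, and every frame is an independent
#' Poisson realisation of 1/n of the accumulated expectation. Granularity
#' (azimuthal spottiness) decreases as the crystallite count grows — many
#' crystallites blend into smooth rings.
#'
#' @param phantom A [phantom_spec()].
#' @param cfg An [experiment_config()].
#' @param geom A [detector_geometry()].
#' @param rocking_fraction Base orientation probability per reflection.
#' @param spot_sigma_px Gaussian spot width on the detector, pixels.
#' @param spot_counts Expected accumulated counts per diffraction spot.
#' @return A list with `sample_frames`, `buffer_frames` (lists of
#'   `detector_frame`), and the reflection list used (`reflections`;
#'   rings beyond the detector edge are dropped).
#' @export
simulate_detector_series <- function(phantom, cfg = experiment_config(),
                                     geom, rocking_fraction = 0.002,
                                     spot_sigma_px = 1, spot_counts = 2000,
                                     beamstop_px = 6) {
  stopifnot(inherits(geom, "detector_geometry"))
  tt <- .pixel_two_theta(geom)
  tt_max <- max(tt)
  refl <- generate_reflections(phantom$cell, phantom$rules,
                               c(min(tt[tt > 0]), tt_max + 1), cfg$wavelength)
  beyond <- refl$two_theta > tt_max
  if (any(beyond)) {
    message(sum(beyond), " ring(s) beyond the detector edge dropped")
    refl <- refl[!beyond, , drop = FALSE]
  }
  # beamstop: mask the central disk where the direct beam would hit
  rows <- seq_len(geom$n_rows) - geom$beam_center[1]
  cols <- seq_len(geom$n_cols) - geom$beam_center[2]
  r_px_mat <- sqrt(outer(rows^2, cols^2, `+`))
  mask <- r_px_mat <= beamstop_px
  s_px <- s_from_two_theta(pmax(tt, min(tt[!mask & tt > 0])), cfg$wavelength)
  bg_rate <- phantom$background[["A"]] * s_px^(-phantom$background[["p"]]) +
    phantom$background[["C"]]
  # per-pixel scale: normalise to per-pixel counts comparable to 1D bins
  bg_rate <- bg_rate / 50
  bg_rate[mask] <- 0
  t_sample <- cfg$n_sample_frames * cfg$frame_exposure
  t_buffer <- cfg$n_buffer_frames * cfg$frame_exposure

  expected <- bg_rate * t_sample
  ints <- .phantom_intensities(phantom, nrow(refl))
  n_eff <- round(phantom$n_crystallites * phantom$crystal_cell_fraction)
  spots <- .with_seed(cfg$seed * 3 + 7, {
    out <- list()
    if (n_eff > 0 && nrow(refl)) {
      for (k in seq_len(nrow(refl))) {
        p_hit <- min(1, rocking_fraction * refl$multiplicity[k])
        n_hit <- stats::rbinom(1, n_eff, p_hit)
        if (n_hit > 0) {
          phi <- stats::runif(n_hit, 0, 2 * pi)
          out[[length(out) + 1]] <- data.frame(
            r_mm = rep(geom$distance * tan(refl$two_theta[k] * pi / 180), n_hit),
            phi = phi, amp = rep(spot_counts * ints[k] / mean(ints), n_hit))
        }
      }
    }
    out
  })
  kern_hw <- ceiling(3 * spot_sigma_px)
  kx <- (-kern_hw):kern_hw
  kern <- exp(-outer(kx^2, kx^2, `+`) / (2 * spot_sigma_px^2))
  kern <- kern / sum(kern)
  for (sp in spots) {
    for (i in seq_len(nrow(sp))) {
      r_px <- sp$r_mm[i] / geom$pixel_size
      row0 <- round(geom$beam_center[1] + r_px * cos(sp$phi[i]))
      col0 <- round(geom$beam_center[2] + r_px * sin(sp$phi[i]))
      rr <- row0 + kx; cc <- col0 + kx
      ok_r <- rr >= 1 & rr <= geom$n_rows
      ok_c <- cc >= 1 & cc <= geom$n_cols
      if (any(ok_r) && any(ok_c)) {
        expected[rr[ok_r], cc[ok_c]] <- expected[rr[ok_r], cc[ok_c]] +
          sp$amp[i] * kern[ok_r, ok_c, drop = FALSE]
      }
    }
  }
  expected[mask] <- 0
  draw_series <- function(mu_total, n_frames, exposure, seed) {
    .with_seed(seed, lapply(seq_len(n_frames), function(i) {
      detector_frame(matrix(stats::rpois(length(mu_total), mu_total / n_frames),
                            nrow(mu_total), ncol(mu_total)),
                     mask = mask, exposure = exposure)
    }))
  }
  list(
    sample_frames = draw_series(expected, cfg$n_sample_frames,
                                cfg$frame_exposure, cfg$seed * 5 + 3),
    buffer_frames = draw_series(bg_rate * t_buffer, cfg$n_buffer_frames,
                                cfg$frame_exposure, cfg$seed * 5 + 4),
    reflections = refl
  )
}

#' Build a 1:2 dilution series of simulated samples
#'
#' Step j has crystal-cell fraction \eqn{f_0/2^j} (step 0 is the undiluted
#' sample), with independent noise seeds per step and shared background
#' parameters — emulating dilution of infected cells with mock-infected
#' cells, which reduces the number of crystals in the irradiated volume
#' without changing the background.
#'
#' @param phantom A [phantom_spec()]; its `crystal_cell_fraction` is
#'   \eqn{f_0}.
#' @param cfg An [experiment_config()].
#' @param n_steps Number of 1:2 dilution steps (16-fold dilution = 4 steps);
#'   `n_steps + 1` profile pairs are produced.
#' @param grid 2-theta grid.
#' @return A `dilution_series`: tibble `steps` with `step`,
#'   `dilution_factor`, `fraction` and list-columns `sample`, `buffer`.
#' @export
make_dilution_series <- function(phantom, cfg = experiment_config(), n_steps = 4,
                                 grid = seq(0.3, 2.2, by = 0.001)) {
  if (n_steps < 1) stop("n_steps must be at least 1", call. = FALSE)
  f0 <- phantom$crystal_cell_fraction
  steps <- lapply(0:n_steps, function(j) {
    ph <- phantom
    ph$crystal_cell_fraction <- f0 / 2^j
    cfg_j <- cfg
    cfg_j$seed <- cfg$seed + 1000L * j
    pair <- simulate_profile_pair(ph, cfg_j, grid)
    tibble::tibble(step = j, dilution_factor = 2^j, fraction = f0 / 2^j,
                   sample = list(pair$sample), buffer = list(pair$buffer))
  })
  structure(list(steps = dplyr::bind_rows(steps), f0 = f0,
                 label = phantom$label),
            class = "dilution_series")
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf("<dilution_series> %s: %d steps, fractions %s\n", x$label,
              nrow(x$steps) - 1,
              paste(signif(x$steps$fraction, 3), collapse = ", ")))
  invisible(x)
}
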