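#' Orchestrated pipeline runs
#'
#' High-level entry points mirroring the stages of a screening campaign:
#' simulate fixtures, screen profiles, refine a phase. Every simulate run
#' writes a manifest (seed, parameters, file checksums) sufficient to verify
#' bit-identical reproduction. These functions are also the workhorses of
#' the command-line wrapper in `inst/scripts/xrpdscreen`.
#'
#' @param out_dir Writable output directory (created if missing).
#' @param cfg An [experiment_config()]; its `seed` drives all randomness.
#' @param phantoms Character vector of [phantom_preset()] names to simulate.
#' @param grid 2-theta grid for the simulated profiles.
#' @param n_steps If non-NULL, additionally simulate a 1:2 dilution series of
#'   the first phantom with this many steps.
#' @return `run_simulate()`: the manifest list, invisibly; profiles are
#'   written as paired `<label>_sample.dat` / `<label>_buffer.dat` files.
#' @export
run_simulate <- function(out_dir, cfg = experiment_config(),
                         phantoms = c("luc", "impdh", "catb", "hex1", "mock"),
                         grid = seq(0.3, 2.2, by = 0.001), n_steps = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  for (i in seq_along(phantoms)) {
    ph <- phantom_preset(phantoms[i])
    cfg_i <- cfg; cfg_i$seed <- cfg$seed + 17L * i
    pair <- simulate_profile_pair(ph, cfg_i, grid)
    fs <- file.path(out_dir, paste0(phantoms[i], c("_sample.dat", "_buffer.dat")))
    write_dat(pair$sample, fs[1]); write_dat(pair$buffer, fs[2])
    files <- c(files, fs)
  }
  if (!is.null(n_steps)) {
    ph <- phantom_preset(phantoms[1])
    series <- make_dilution_series(ph, cfg, n_steps = n_steps, grid = grid)
    for (j in seq_len(nrow(series$steps))) {
      fs <- file.path(out_dir, sprintf("dilution_step%d_%s.dat",
                                       series$steps$step[j], c("sample", "buffer")))
      write_dat(series$steps$sample[[j]], fs[1])
      write_dat(series$steps$buffer[[j]], fs[2])
      files <- c(files, fs)
    }
  }
  manifest <- list(
    seed = cfg$seed,
    config = cfg[c("wavelength", "distance", "beam_w", "beam_h",
                   "capillary_path", "n_sample_frames", "n_buffer_frames",
                   "frame_exposure", "readout")],
    phantoms = phantoms,
    grid = list(min = min(grid), max = max(grid), n = length(grid)),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @rdname run_simulate
#' @param profiles Character vector of `.dat` paths, or a named list of
#'   `xrd_pattern`s. Files named `*_sample.dat` are paired with a sibling
#'   `*_buffer.dat` when one exists.
#' @param wavelength Wavelength used to convert s-axis profiles to 2-theta.
#' @param ... Screening options passed to [classify_crystal_content()].
#' @return `run_screen()`: a tibble with one row per sample (`sample`,
#'   `crystal_present`, `score`, `n_peaks`, `n_significant`).
#' @export
run_screen <- function(profiles, wavelength = 1.24, ...) {
  if (is.character(profiles)) {
    paths <- profiles
    profiles <- list()
    for (p in paths) {
      if (!file.exists(p)) stop("cannot read profile file: ", p, call. = FALSE)
      pat <- tryCatch(read_dat(p),
                      error = function(e) stop("parse failure in ", p, ": ",
                                               conditionMessage(e), call. = FALSE))
      buf_path <- sub("_sample\\.dat$", "_buffer.dat", p)
      entry <- list(sample = pat)
      if (buf_path != p && file.exists(buf_path)) entry$buffer <- read_dat(buf_path)
      profiles[[tools::file_path_sans_ext(basename(p))]] <- entry
    }
  } else {
    profiles <- lapply(profiles, function(p) if (inherits(p, "xrd_pattern")) list(sample = p) else p)
  }
  rows <- purrr::imap(profiles, function(entry, id) {
    smp <- entry$sample
    if (axis_kind(smp) != "two_theta_deg") smp <- convert_axis(smp, wavelength)
    ref <- entry$buffer
    if (!is.null(ref) && axis_kind(ref) != "two_theta_deg") {
      ref <- convert_axis(ref, wavelength)
    }
    res <- classify_crystal_content(smp, reference = ref, ...)
    dplyr::mutate(glance(res), sample = id, .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' @rdname run_simulate
#' @param profile An `xrd_pattern` or `.dat` path (s or 2-theta axis;
#'   auto-converted).
#' @param start_cell A [unit_cell()] with starting lattice parameters.
#' @param spacegroup Space-group symbol (see [space_group()]).
#' @param window 2-theta fit window in degrees (defaults to the profile
#'   range trimmed by 2%).
#' @param n_background Number of Chebyshev background terms (10–14 typical;
#'   default 12).
#' @param start_profile Starting [profile_params()] (peak width/shape).
#' @param config A [pawley_config()].
#' @param report_prefix If non-NULL, write the fit report files here.
#' @return `run_refine()`: a `pawley_fit`.
#' @export
run_refine <- function(profile, start_cell, spacegroup, wavelength = 1.24,
                       window = NULL, n_background = 12,
                       start_profile = profile_params(eta = 0.4, W = 2.5e-4),
                       config = pawley_config(), report_prefix = NULL) {
  if (is.character(profile)) profile <- read_dat(profile)
  if (axis_kind(profile) != "two_theta_deg") {
    profile <- convert_axis(profile, wavelength)
  }
  rules <- space_group(spacegroup)
  if (is.null(window)) {
    rng <- range(profile$axis)
    window <- rng + c(0.02, -0.02) * diff(rng)
  }
  keep <- profile$axis >= window[1] & profile$axis <= window[2]
  obs <- pattern1d(profile$axis[keep], profile$intensity[keep],
                   profile$sigma[keep], axis_kind = "two_theta_deg",
                   meta = pattern_meta(profile))
  prof <- start_profile
  start <- pawley_model(start_cell, rules, wavelength, window, profile = prof,
                        background = background_model(numeric(n_background), window))
  start$reflections$intensity <- equipartition_init(start$reflections, prof, obs)
  fit <- pawley_refine(obs, start, config)
  if (!is.null(report_prefix)) write_pawley_report(fit, report_prefix)
  fit
}
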