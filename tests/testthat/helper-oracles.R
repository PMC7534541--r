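# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity so they cannot share a
# bug with the vectorised implementation they check.

# Structure-factor cancellation oracle for systematic absences: a reflection
# is absent iff the structure factor of a single general-position orbit
# vanishes for arbitrary atom positions. Checked over several random general
# positions.
sf_absent_oracle <- function(rules, hkl, n_positions = 5) {
  h <- as.numeric(hkl)
  all(vapply(seq_len(n_positions), function(i) {
    x <- stats::runif(3)
    f <- sum(vapply(rules$operators, function(op) {
      phase <- 2 * pi * sum(h * (op$R %*% x + op$t))
      complex(real = cos(phase), imaginary = sin(phase))
    }, complex(1)))
    Mod(f) < 1e-8 * length(rules$operators)
  }, logical(1)))
}

# Naive per-pixel azimuthal binning: explicit double loop.
azimuthal_oracle <- function(counts, mask, geom, n_bins, edges = NULL) {
  tt <- matrix(0, nrow(counts), ncol(counts))
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      r <- sqrt((i - geom$beam_center[1])^2 + (j - geom$beam_center[2])^2) *
        geom$pixel_size
      tt[i, j] <- atan(r / geom$distance) * 180 / pi
    }
  }
  tts <- tt[!mask]
  cs <- counts[!mask]
  if (is.null(edges)) edges <- seq(min(tts), max(tts), length.out = n_bins + 1)
  sums <- numeric(n_bins); npx <- integer(n_bins)
  for (p in seq_along(tts)) {
    b <- findInterval(tts[p], edges, rightmost.closed = TRUE, all.inside = TRUE)
    sums[b] <- sums[b] + cs[p]; npx[b] <- npx[b] + 1L
  }
  keep <- npx > 0
  list(centers = ((edges[-1] + edges[-(n_bins + 1)]) / 2)[keep],
       mean = sums[keep] / npx[keep], n_pix = npx[keep])
}

# Chebyshev series by the three-term recurrence.
cheb_oracle <- function(coeffs, x) {
  vapply(x, function(xi) {
    tkm1 <- 1; tk <- xi
    total <- coeffs[1] * tkm1
    if (length(coeffs) > 1) total <- total + coeffs[2] * tk
    if (length(coeffs) > 2) {
      for (j in 3:length(coeffs)) {
        tkp1 <- 2 * xi * tk - tkm1
        total <- total + coeffs[j] * tkp1
        tkm1 <- tk; tk <- tkp1
      }
    }
    total
  }, numeric(1))
}

# Brute-force reflection enumeration: count of allowed, in-window lattice
# planes before any symmetry merging.
brute_reflection_count <- function(cell, rules, range_deg, wavelength, h_max) {
  n <- 0
  ds <- c()
  for (h in -h_max:h_max) for (k in -h_max:h_max) for (l in -h_max:h_max) {
    if (h == 0 && k == 0 && l == 0) next
    d <- d_spacing(cell, c(h, k, l))
    x <- wavelength / (2 * d)
    if (x > 1) next
    tt <- 2 * asin(x) * 180 / pi
    if (tt > range_deg[1] && tt <= range_deg[2] &&
        !is_systematically_absent(rules, c(h, k, l))) {
      n <- n + 1
      ds <- c(ds, d)
    }
  }
  list(n = n, d = ds)
}

# Flat-background profile with unit-area Gaussian peaks and known constant
# noise sigma; used for deterministic screening tests.
make_peak_profile <- function(grid, centers, heights, fwhm = 0.02,
                              background = 100, noise_sd = 0, sigma = NULL,
                              seed = NULL) {
  y <- rep(background, length(grid))
  for (i in seq_along(centers)) {
    y <- y + heights[i] * exp(-4 * log(2) * ((grid - centers[i]) / fwhm)^2)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(grid), 0, noise_sd)
  }
  if (is.null(sigma)) sigma <- rep(max(noise_sd, 1e-6), length(grid))
  pattern1d(grid, y, sigma, axis_kind = "two_theta_deg")
}

paper_cells <- list(
  catb = list(cell = unit_cell("tetragonal", 125.69, c = 54.408), sg = "P42212"),
  hex1 = list(cell = unit_cell("hexagonal", 58.01, c = 195.2), sg = "P6522")
)
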