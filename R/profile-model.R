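#' Pseudo-Voigt peak profile
#'
#' Unit-area linear mixture of a Lorentzian and a Gaussian of common FWHM:
#' \eqn{PV(x) = \eta L(x;\Gamma) + (1-\eta) G(x;\Gamma)}. This is the
#' standard Bragg peak shape for whole-powder-pattern fitting.
#'
#' @param x Offset from the peak centre, degrees.
#' @param gamma Full width at half maximum, degrees, positive.
#' @param eta Lorentzian mixing fraction in `[0, 1]`.
#' @return Profile values; the numeric integral over x is 1.
#' @examples
#' pseudo_voigt(0, gamma = 0.02, eta = 0)   # Gaussian apex 2*sqrt(ln 2/pi)/gamma
#' @export
pseudo_voigt <- function(x, gamma, eta) {
  if (any(gamma <= 0)) stop("gamma must be positive", call. = FALSE)
  if (any(eta < 0 | eta > 1)) stop("eta must lie in [0, 1]", call. = FALSE)
  g <- (2 / gamma) * sqrt(log(2) / pi) * exp(-4 * log(2) * (x / gamma)^2)
  l <- (2 / (pi * gamma)) / (1 + 4 * (x / gamma)^2)
  eta * l + (1 - eta) * g
}

#' Caglioti angular FWHM variation
#'
#' \eqn{\Gamma(\theta) = \sqrt{U\tan^2\theta + V\tan\theta + W}} — the
#' standard description of peak-width variation over the 2-theta range.
#'
#' @param theta Bragg angle \eqn{\theta} (half the scattering angle), degrees.
#' @param U,V,W Caglioti coefficients in squared degrees.
#' @return FWHM in degrees.
#' @export
fwhm_caglioti <- function(theta, U, V, W) {
  t <- tan(theta * pi / 180)
  g2 <- U * t^2 + V * t + W
  if (any(g2 <= 0)) stop("Caglioti FWHM^2 must be positive over the range", call. = FALSE)
  sqrt(g2)
}

#' Profile-shape parameters
#'
#' @param eta Lorentzian fraction in `[0,1]`.
#' @param U,V,W Caglioti coefficients (deg^2).
#' @param asym Single peak-asymmetry coefficient; 0 (default) = symmetric.
#' @return A `profile_params` object.
#' @export
profile_params <- function(eta = 0.5, U = 0, V = 0, W = 4e-4, asym = 0) {
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]", call. = FALSE)
  structure(list(eta = eta, U = U, V = V, W = W, asym = asym),
            class = "profile_params")
}

#' Shifted-Chebyshev background model
#'
#' The background under a powder pattern is modelled as a Chebyshev
#' polynomial series on the fit window, \eqn{\sum_j c_j T_j(x)} with
#' \eqn{x} the affine map of `domain` onto `[-1, 1]`; around 10–14 terms are
#' typical for cell-suspension backgrounds.
#'
#' @param coeffs Ordered coefficients `c_0, c_1, ...`.
#' @param domain Length-2 `(two_theta_min, two_theta_max)` mapped to `[-1,1]`.
#' @return A `background_model` object.
#' @export
background_model <- function(coeffs, domain) {
  domain <- as.numeric(domain)
  if (length(domain) != 2 || domain[1] >= domain[2]) {
    stop("domain bounds must be strictly ordered", call. = FALSE)
  }
  structure(list(coeffs = as.numeric(coeffs), domain = domain),
            class = "background_model")
}

# Chebyshev design matrix T_0..T_{n-1}(x) on [-1,1] via the closed form
# T_j(x) = cos(j*acos(x)).
.cheb_design <- function(x, n_terms) {
  x <- pmin(1, pmax(-1, x))
  outer(acos(x), seq_len(n_terms) - 1, function(a, j) cos(j * a))
}

#' @rdname background_model
#' @param bg A `background_model`.
#' @param grid 2-theta values inside the domain.
#' @export
eval_background <- function(bg, grid) {
  stopifnot(inherits(bg, "background_model"))
  eps <- 1e-9 * diff(bg$domain)
  if (any(grid < bg$domain[1] - eps | grid > bg$domain[2] + eps)) {
    stop("grid extends outside the background domain", call. = FALSE)
  }
  x <- (2 * grid - sum(bg$domain)) / diff(bg$domain)
  drop(.cheb_design(x, length(bg$coeffs)) %*% bg$coeffs)
}

#' Pawley model of a powder pattern
#'
#' Bundles everything needed to simulate a pattern without an atomic
#' structure: unit cell and space group (peak positions), instrumental zero
#' shift, pseudo-Voigt profile parameters, Chebyshev background, and one free
#' intensity per merged reflection class.
#'
#' @param cell A [unit_cell()].
#' @param rules A [space_group()].
#' @param wavelength Wavelength in Angstrom.
#' @param two_theta_range Modelled window, degrees.
#' @param zero_shift Instrumental angular offset added to every calculated
#'   peak position, degrees (bounded to |Z| < 0.1 deg).
#' @param profile A [profile_params()].
#' @param background A [background_model()] (defaults to zero background on
#'   the window).
#' @param intensities Per-reflection intensities; defaults to 0. Length must
#'   match the generated reflection list.
#' @return A `pawley_model`; its `reflections` field is the
#'   [generate_reflections()] tibble with an `intensity` column.
#' @export
pawley_model <- function(cell, rules, wavelength, two_theta_range,
                         zero_shift = 0, profile = profile_params(),
                         background = NULL, intensities = NULL) {
  if (abs(zero_shift) >= 0.1) stop("|zero_shift| must be < 0.1 deg", call. = FALSE)
  refl <- generate_reflections(cell, rules, two_theta_range, wavelength)
  if (is.null(intensities)) intensities <- rep(0, nrow(refl))
  if (length(intensities) != nrow(refl)) {
    stop("intensities length (", length(intensities),
         ") does not match reflection count (", nrow(refl), ")", call. = FALSE)
  }
  if (any(intensities < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (is.null(background)) background <- background_model(0, two_theta_range)
  refl$intensity <- as.numeric(intensities)
  structure(
    list(cell = cell, rules = rules, wavelength = wavelength,
         two_theta_range = sort(as.numeric(two_theta_range)),
         zero_shift = zero_shift, profile = profile, background = background,
         reflections = refl),
    class = "pawley_model"
  )
}

#' @export
print.pawley_model <- function(x, ...) {
  cat(sprintf("<pawley_model> %s, %s; %d reflections in (%.3g, %.3g) deg; Z = %.4g deg\n",
              format(x$cell), x$rules$symbol, nrow(x$reflections),
              x$two_theta_range[1], x$two_theta_range[2], x$zero_shift))
  invisible(x)
}

# Bragg component only (no background), on a 2-theta grid.
.bragg_component <- function(model, grid) {
  refl <- model$reflections
  y <- numeric(length(grid))
  if (!nrow(refl)) return(y)
  pos <- refl$two_theta + model$zero_shift
  prof <- model$profile
  gamma <- fwhm_caglioti(pos / 2, prof$U, prof$V, prof$W)
  for (k in seq_len(nrow(refl))) {
    amp <- refl$intensity[k] * refl$multiplicity[k]
    if (amp == 0) next
    y <- y + amp * pseudo_voigt(grid - pos[k], gamma[k], prof$eta)
  }
  y
}

#' Simulate a powder profile from a Pawley model
#'
#' \eqn{y(2\theta) = B(2\theta) + \sum_k I_k m_k PV(2\theta - (2\theta_k + Z);
#' \Gamma(\theta_k), \eta)} with \eqn{m_k} the reflection multiplicity.
#' Deterministic; attach counting noise with the synthetic-data generator if
#' a noisy realisation is wanted.
#'
#' @param model A [pawley_model()].
#' @param grid Increasing 2-theta values.
#' @param sigma Optional per-point sigmas for the returned pattern (defaults
#'   to a small constant; the simulation itself is noise-free).
#' @return An `xrd_pattern` on the 2-theta axis.
#' @export
simulate_profile <- function(model, grid, sigma = NULL) {
  stopifnot(inherits(model, "pawley_model"))
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  y <- eval_background(model$background, grid) + .bragg_component(model, grid)
  if (is.null(sigma)) sigma <- rep(max(abs(y), 1) * 1e-6, length(grid))
  pattern1d(grid, y, sigma, axis_kind = "two_theta_deg",
            meta = list(simulated = TRUE, space_group = model$rules$symbol))
}
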