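#' Construct a unit cell
#'
#' A light-weight record of lattice parameters restricted to the lattice
#' systems that occur in protein powder screening of tetragonal and hexagonal
#' in cellulo crystals, plus orthorhombic and cubic cells for generality.
#' Angles are implied by the system (and checked if supplied).
#'
#' @param system One of `"tetragonal"`, `"hexagonal"`, `"orthorhombic"`,
#'   `"cubic"`.
#' @param a,b,c Lattice lengths in Angstrom. `b` defaults to `a`; for cubic
#'   cells `c` defaults to `a` as well; for tetragonal/hexagonal cells `c`
#'   must be given.
#' @return An object of class `unit_cell` with fields `system`, `a`, `b`,
#'   `c`, `alpha`, `beta`, `gamma`.
#' @examples
#' unit_cell("tetragonal", a = 125.69, c = 54.408)  # CatB-like cell
#' unit_cell("hexagonal", a = 58.01, c = 195.2)     # HEX-1-like cell
#' @export
unit_cell <- function(system = c("tetragonal", "hexagonal", "orthorhombic", "cubic"),
                      a, b = a, c = NULL) {
  system <- match.arg(system)
  if (system == "cubic" && is.null(c)) c <- a
  if (is.null(c)) stop("c must be supplied for non-cubic cells", call. = FALSE)
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (a <= 0 || b <= 0 || c <= 0) stop("lattice lengths must be positive", call. = FALSE)
  ang <- switch(system,
    tetragonal   = c(90, 90, 90),
    hexagonal    = c(90, 90, 120),
    orthorhombic = c(90, 90, 90),
    cubic        = c(90, 90, 90)
  )
  if (system %in% c("tetragonal", "hexagonal") && !isTRUE(all.equal(a, b))) {
    stop("a and b must be equal for ", system, " cells", call. = FALSE)
  }
  if (system == "cubic" && !(isTRUE(all.equal(a, b)) && isTRUE(all.equal(a, c)))) {
    stop("a, b and c must be equal for cubic cells", call. = FALSE)
  }
  structure(
    list(system = system, a = a, b = b, c = c,
         alpha = ang[1], beta = ang[2], gamma = ang[3]),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> %s  a = %.4g  b = %.4g  c = %.4g A  (%g, %g, %g deg)\n",
              x$system, x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' @export
format.unit_cell <- function(x, ...) {
  sprintf("%s a=%.6g b=%.6g c=%.6g", x$system, x$a, x$b, x$c)
}

#' d-spacing of a lattice plane
#'
#' Evaluates the standard quadratic forms: tetragonal
#' \eqn{1/d^2 = (h^2+k^2)/a^2 + l^2/c^2}, hexagonal
#' \eqn{1/d^2 = 4(h^2+hk+k^2)/(3a^2) + l^2/c^2}, orthorhombic
#' \eqn{1/d^2 = h^2/a^2 + k^2/b^2 + l^2/c^2} (cubic as a special case).
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer Miller indices: a length-3 vector or a 3-column matrix
#'   (one reflection per row).
#' @return d-spacings in Angstrom (one per row of `hkl`).
#' @examples
#' d_spacing(unit_cell("tetragonal", 125.69, c = 54.408), c(1, 0, 0))  # = a
#' @export
d_spacing <- function(cell, hkl) {
  stopifnot(inherits(cell, "unit_cell"))
  m <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  if (ncol(m) != 3) stop("hkl must have 3 columns", call. = FALSE)
  if (any(rowSums(m != 0) == 0)) stop("hkl = (0,0,0) has no d-spacing", call. = FALSE)
  h <- m[, 1]; k <- m[, 2]; l <- m[, 3]
  inv_d2 <- switch(cell$system,
    tetragonal   = (h^2 + k^2) / cell$a^2 + l^2 / cell$c^2,
    cubic        = (h^2 + k^2 + l^2) / cell$a^2,
    orthorhombic = h^2 / cell$a^2 + k^2 / cell$b^2 + l^2 / cell$c^2,
    hexagonal    = 4 * (h^2 + h * k + k^2) / (3 * cell$a^2) + l^2 / cell$c^2
  )
  unname(1 / sqrt(inv_d2))
}
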