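#' Generate the reflection list for a cell and space group
#'
#' Enumerates all lattice planes whose Bragg angle falls inside a 2-theta
#' window, removes systematically absent classes, merges symmetry-equivalent
#' reflections into one entry per class with its multiplicity, and orders the
#' list by ascending angle. This is the peak-position fingerprint that a
#' powder profile of the phase must show.
#'
#' Merged classes are keyed on symmetry equivalence (not d-spacing alone), so
#' accidentally degenerate classes stay separate entries; the representative
#' `hkl` of a class is the lexicographically greatest orbit member.
#'
#' @param cell A [unit_cell()].
#' @param rules A [space_group()] whose `system` matches the cell.
#' @param two_theta_range Numeric length-2, degrees, within (0, 180).
#' @param wavelength Wavelength in Angstrom.
#' @return A tibble with columns `h`, `k`, `l`, `d` (A), `two_theta` (deg),
#'   `s` (1/A), `multiplicity`, sorted by ascending `two_theta`.
#' @examples
#' cell <- unit_cell("hexagonal", a = 58.01, c = 195.2)
#' generate_reflections(cell, space_group("P6522"), c(0.4, 2.0), 1.24)
#' @export
generate_reflections <- function(cell, rules, two_theta_range, wavelength) {
  stopifnot(inherits(cell, "unit_cell"), inherits(rules, "space_group"))
  if (cell$system != rules$system) {
    stop("cell system (", cell$system, ") does not match space group system (",
         rules$system, ")", call. = FALSE)
  }
  tt <- sort(as.numeric(two_theta_range))
  if (length(tt) != 2 || tt[1] < 0 || tt[2] >= 180) {
    stop("two_theta_range must lie within [0, 180)", call. = FALSE)
  }
  if (tt[2] <= 0 || tt[1] == tt[2]) return(.empty_reflections())

  d_min <- d_from_two_theta(tt[2], wavelength)
  # index bounds from the largest reciprocal step per axis
  h_max <- ceiling(cell$a / d_min)
  k_max <- ceiling(cell$b / d_min)
  l_max <- ceiling(cell$c / d_min)
  if (cell$system == "hexagonal") {
    h_max <- k_max <- ceiling(2 * cell$a / (sqrt(3) * d_min))
  }
  grid <- expand.grid(h = -h_max:h_max, k = -k_max:k_max, l = -l_max:l_max)
  grid <- grid[rowSums(grid != 0) > 0, , drop = FALSE]
  m <- as.matrix(grid)

  d <- d_spacing(cell, m)
  sin_th <- wavelength / (2 * d)
  keep <- sin_th <= 1
  m <- m[keep, , drop = FALSE]; d <- d[keep]
  two_theta <- 2 * asin(wavelength / (2 * d)) * 180 / pi
  inside <- two_theta > tt[1] & two_theta <= tt[2]
  m <- m[inside, , drop = FALSE]; d <- d[inside]; two_theta <- two_theta[inside]
  if (!nrow(m)) return(.empty_reflections())
  keep <- !is_systematically_absent(rules, m)
  m <- m[keep, , drop = FALSE]; d <- d[keep]; two_theta <- two_theta[keep]
  if (!nrow(m)) return(.empty_reflections())

  canon <- t(apply(m, 1, function(x) canonical_hkl(rules, x)))
  key <- paste(canon[, 1], canon[, 2], canon[, 3])
  idx <- !duplicated(key)
  mult <- as.integer(table(key)[key[idx]])
  d_u <- d[idx]; tt_u <- two_theta[idx]
  out <- tibble::tibble(
    h = as.integer(canon[idx, 1]),
    k = as.integer(canon[idx, 2]),
    l = as.integer(canon[idx, 3]),
    d = d_u,
    two_theta = tt_u,
    s = 2 * pi / d_u,
    multiplicity = mult
  )
  dplyr::arrange(out, .data$two_theta, dplyr::desc(.data$h), dplyr::desc(.data$k),
                 dplyr::desc(.data$l))
}

.empty_reflections <- function() {
  tibble::tibble(h = integer(), k = integer(), l = integer(), d = numeric(),
                 two_theta = numeric(), s = numeric(), multiplicity = integer())
}

#' Write a reflection table as tab-separated text
#'
#' Columns: `hkl`, `d` (A), `two_theta` (deg), `s` (1/A), `multiplicity`,
#' plus `intensity` if present — the column set of a refined-reflection
#' supplementary table.
#'
#' @param reflections A tibble from [generate_reflections()] (optionally with
#'   an `intensity` column from a Pawley fit).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reflection_table <- function(reflections, path) {
  df <- data.frame(
    hkl = sprintf("%d %d %d", reflections$h, reflections$k, reflections$l),
    d_A = reflections$d,
    two_theta_deg = reflections$two_theta,
    s_invA = reflections$s,
    multiplicity = reflections$multiplicity
  )
  if ("intensity" %in% names(reflections)) df$intensity <- reflections$intensity
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
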