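#' 1D powder/scattering patterns
#'
#' A pattern is a tibble with columns `axis`, `intensity`, `sigma` plus two
#' attributes: `axis_kind` (`"s_inv_angstrom"` or `"two_theta_deg"`) and a
#' free-form `meta` list (sample id, frames summed, wavelength, ...). It is
#' the central currency of the pipeline: azimuthal integration produces one,
#' screening and Pawley fitting consume one.
#'
#' @param axis Strictly increasing axis values (s in 1/A or 2-theta in deg).
#' @param intensity Intensities (may be negative after buffer subtraction).
#' @param sigma Per-point uncertainties, strictly positive.
#' @param axis_kind `"s_inv_angstrom"` or `"two_theta_deg"`.
#' @param meta Named list of provenance fields.
#' @return A tibble of class `xrd_pattern`.
#' @examples
#' p <- pattern1d(seq(0.4, 2, by = 0.01), rexp(161) + 10, sigma = rep(1, 161),
#'                axis_kind = "two_theta_deg")
#' @export
pattern1d <- function(axis, intensity, sigma,
                      axis_kind = c("two_theta_deg", "s_inv_angstrom"),
                      meta = list()) {
  axis_kind <- match.arg(axis_kind)
  axis <- as.numeric(axis); intensity <- as.numeric(intensity); sigma <- as.numeric(sigma)
  n <- length(axis)
  if (length(intensity) != n || length(sigma) != n) {
    stop("axis, intensity and sigma must have equal length", call. = FALSE)
  }
  if (n >= 2 && any(diff(axis) <= 0)) stop("axis must be strictly increasing", call. = FALSE)
  if (any(sigma <= 0) || any(!is.finite(sigma))) {
    stop("sigma must be strictly positive", call. = FALSE)
  }
  out <- tibble::tibble(axis = axis, intensity = intensity, sigma = sigma)
  class(out) <- c("xrd_pattern", class(out))
  attr(out, "axis_kind") <- axis_kind
  attr(out, "meta") <- meta
  out
}

#' @rdname pattern1d
#' @param p An `xrd_pattern`.
#' @export
axis_kind <- function(p) attr(p, "axis_kind") %||% "two_theta_deg"

#' @rdname pattern1d
#' @export
pattern_meta <- function(p) attr(p, "meta") %||% list()

.assert_pattern <- function(p, arg = "pattern") {
  if (!inherits(p, "xrd_pattern")) stop(arg, " must be an xrd_pattern", call. = FALSE)
  invisible(p)
}

#' @export
print.xrd_pattern <- function(x, ...) {
  cat(sprintf("<xrd_pattern> %d points on %s axis [%g, %g]\n",
              nrow(x), axis_kind(x), min(x$axis), max(x$axis)))
  NextMethod()
}

#' Subtract a buffer/background pattern
#'
#' Point-by-point subtraction of a buffer (e.g. TBS control) measurement from
#' a sample measurement on the identical axis grid, with uncertainty
#' propagation \eqn{\sigma = \sqrt{\sigma_s^2 + k^2 \sigma_b^2}}. No silent
#' interpolation: mismatched grids are an error. Negative differences are
#' retained — they carry the noise statistics that peak significance tests
#' rely on.
#'
#' @param sample,buffer `xrd_pattern`s on identical grids and axis kinds.
#' @param scale Global scale applied to the buffer before subtraction
#'   (default 1, plain subtraction; a transmission factor can be supplied).
#' @return An `xrd_pattern` of the difference.
#' @export
subtract_buffer <- function(sample, buffer, scale = 1) {
  .assert_pattern(sample, "sample"); .assert_pattern(buffer, "buffer")
  if (axis_kind(sample) != axis_kind(buffer)) {
    stop("sample and buffer have different axis kinds", call. = FALSE)
  }
  if (nrow(sample) != nrow(buffer) ||
      max(abs(sample$axis - buffer$axis)) > 1e-9 * max(abs(sample$axis))) {
    stop("sample and buffer are not on the same axis grid", call. = FALSE)
  }
  pattern1d(
    sample$axis,
    sample$intensity - scale * buffer$intensity,
    sqrt(sample$sigma^2 + scale^2 * buffer$sigma^2),
    axis_kind = axis_kind(sample),
    meta = utils::modifyList(pattern_meta(sample),
                             list(buffer_subtracted = TRUE, buffer_scale = scale))
  )
}

#' Convert a pattern between s and 2-theta axes
#'
#' Transforms the axis point-by-point via \eqn{s = 4\pi\sin(\theta)/\lambda};
#' intensities and sigmas are carried unchanged (no Jacobian re-weighting),
#' matching the convention of converting I(s) profiles to I(2-theta) for
#' powder-diffraction software.
#'
#' @param p An `xrd_pattern`.
#' @param wavelength Wavelength in Angstrom.
#' @param target Target axis kind.
#' @return An `xrd_pattern` on the target axis.
#' @export
convert_axis <- function(p, wavelength,
                         target = c("two_theta_deg", "s_inv_angstrom")) {
  .assert_pattern(p)
  target <- match.arg(target)
  if (wavelength <= 0) stop("wavelength must be positive", call. = FALSE)
  if (axis_kind(p) == target) return(p)
  new_axis <- if (target == "two_theta_deg") {
    two_theta_from_s(p$axis, wavelength)
  } else {
    s_from_two_theta(p$axis, wavelength)
  }
  pattern1d(new_axis, p$intensity, p$sigma, axis_kind = target,
            meta = utils::modifyList(pattern_meta(p), list(wavelength = wavelength)))
}

#' Read and write 3-column scattering profiles
#'
#' The on-disk dialect is whitespace-separated text with `#`-prefixed header
#' lines, three columns (axis, intensity, uncertainty) — the format used for
#' deposited 1D solution-scattering profiles. The reader accepts momentum
#' transfer declared in either 1/Angstrom or 1/nm (values are normalised to
#' 1/Angstrom by dividing by 10) and 2-theta in degrees.
#'
#' @param path File path.
#' @param p Pattern to write.
#' @return `read_dat()` returns an `xrd_pattern`; `write_dat()` returns
#'   `path` invisibly.
#' @export
read_dat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[grepl("^\\s*#", lines)]
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("no data rows in ", path, call. = FALSE)
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  fields <- fields[nf >= 2]
  vals <- t(vapply(fields, function(f) {
    x <- suppressWarnings(as.numeric(f[1:3]))
    if (is.na(x[3])) x[3] <- NA_real_
    x
  }, numeric(3)))
  vals <- vals[stats::complete.cases(vals[, 1:2]), , drop = FALSE]
  hdr_txt <- tolower(paste(hdr, collapse = " "))
  kind <- if (grepl("two[_ -]?theta|2theta|2-theta", hdr_txt)) "two_theta_deg" else "s_inv_angstrom"
  axis <- vals[, 1]
  if (kind == "s_inv_angstrom" &&
      grepl("nm\\^?-1|1/nm|inverse nm|nm-1", hdr_txt)) {
    axis <- axis / 10
  }
  sigma <- vals[, 3]
  if (all(is.na(sigma))) sigma <- rep(max(abs(vals[, 2])) * 1e-3 + 1e-12, length(axis))
  ord <- order(axis)
  pattern1d(axis[ord], vals[ord, 2], sigma[ord], axis_kind = kind,
            meta = list(source = path, header = hdr))
}

#' @rdname read_dat
#' @export
write_dat <- function(p, path) {
  .assert_pattern(p)
  unit <- if (axis_kind(p) == "two_theta_deg") "two_theta (deg)" else "s (1/A)"
  meta <- pattern_meta(p)
  hdr <- c(
    "# xrpdscreen 1D pattern",
    paste0("# axis: ", unit),
    "# columns: axis intensity sigma"
  )
  keep <- vapply(meta, function(v) is.atomic(v) && length(v) == 1, logical(1))
  if (any(keep)) {
    hdr <- c(hdr, sprintf("# %s: %s", names(meta)[keep], unlist(meta[keep])))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(data.frame(p$axis, p$intensity, p$sigma), con,
                     sep = "  ", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @importFrom rlang %||%
NULL

#' Plot a 1D pattern
#'
#' @param object An `xrd_pattern`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.xrd_pattern <- function(object, ...) {
  xlab <- if (axis_kind(object) == "two_theta_deg") {
    expression(2 * theta ~ "(deg)")
  } else {
    expression(s ~ ("Å"^-1))
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$axis, y = .data$intensity)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$intensity - .data$sigma,
                                      ymax = .data$intensity + .data$sigma),
                         fill = "grey80") +
    ggplot2::geom_line(colour = "black") +
    ggplot2::labs(x = xlab, y = "Intensity (counts)") +
    ggplot2::theme_minimal()
}
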