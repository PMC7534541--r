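#' Detector geometry and frames
#'
#' `detector_geometry()` records the mapping from pixel position to
#' scattering angle for a flat detector normal to the beam:
#' \eqn{2\theta = \arctan(r/D)} with \eqn{r} the in-plane distance of the
#' pixel centre from the beam centre and \eqn{D} the sample–detector
#' distance. `detector_frame()` wraps a non-negative integer count image with
#' a mask (TRUE = excluded pixel) and the accumulated exposure time.
#'
#' @param distance Sample–detector distance in mm (e.g. 3000 for a 3 m
#'   bioSAXS setup).
#' @param pixel_size Pixel edge in mm.
#' @param beam_center Length-2 numeric `(row, col)` in pixel units (1-based,
#'   fractional allowed).
#' @param wavelength Wavelength in Angstrom.
#' @param n_rows,n_cols Image dimensions in pixels.
#' @return `detector_geometry()`: a `detector_geometry` object;
#'   `detector_frame()`: a `detector_frame` object.
#' @export
detector_geometry <- function(distance, pixel_size, beam_center, wavelength,
                              n_rows, n_cols) {
  stopifnot(distance > 0, pixel_size > 0, wavelength > 0,
            length(beam_center) == 2, n_rows >= 1, n_cols >= 1)
  structure(
    list(distance = distance, pixel_size = pixel_size,
         beam_center = as.numeric(beam_center), wavelength = wavelength,
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
    class = "detector_geometry"
  )
}

#' @rdname detector_geometry
#' @param counts Matrix of non-negative counts.
#' @param mask Logical matrix, `TRUE` for excluded pixels (defaults to none).
#' @param exposure Exposure time in seconds.
#' @export
detector_frame <- function(counts, mask = NULL, exposure = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(mask)) mask <- matrix(FALSE, nrow(counts), ncol(counts))
  mask <- as.matrix(mask)
  if (!identical(dim(counts), dim(mask))) {
    stop("counts and mask must share dimensions", call. = FALSE)
  }
  if (exposure <= 0) stop("exposure must be positive", call. = FALSE)
  structure(list(counts = counts, mask = mask, exposure = exposure),
            class = "detector_frame")
}

#' @export
print.detector_frame <- function(x, ...) {
  cat(sprintf("<detector_frame> %d x %d px, %d masked, %.3g s, %.4g total counts\n",
              nrow(x$counts), ncol(x$counts), sum(x$mask), x$exposure,
              sum(x$counts[!x$mask])))
  invisible(x)
}

#' Sum a series of detector frames
#'
#' Elementwise summation of the frames collected during the course of an
#' exposure (e.g. 40 frames of 0.045 s each) into one accumulated image;
#' exposures add, the common mask is preserved.
#'
#' @param frames List of `detector_frame`s with identical shapes and masks.
#' @return A single `detector_frame`.
#' @export
sum_frames <- function(frames) {
  if (!length(frames)) stop("empty frame list", call. = FALSE)
  ref <- frames[[1]]
  for (f in frames[-1]) {
    if (!identical(dim(f$counts), dim(ref$counts))) {
      stop("frames differ in shape", call. = FALSE)
    }
    if (!identical(f$mask, ref$mask)) stop("frames differ in mask", call. = FALSE)
  }
  detector_frame(
    Reduce(`+`, lapply(frames, `[[`, "counts")),
    mask = ref$mask,
    exposure = sum(vapply(frames, `[[`, numeric(1), "exposure"))
  )
}

# per-pixel 2-theta (degrees) for a geometry
.pixel_two_theta <- function(geom) {
  rows <- seq_len(geom$n_rows) - geom$beam_center[1]
  cols <- seq_len(geom$n_cols) - geom$beam_center[2]
  r <- sqrt(outer(rows^2, cols^2, `+`)) * geom$pixel_size
  atan(r / geom$distance) * 180 / pi
}

#' Azimuthal (radial) integration of a detector frame
#'
#' Reduces a 2D image to a 1D powder profile: every unmasked pixel is
#' assigned to a 2-theta bin by its centre angle (no pixel splitting), each
#' bin reports the mean count of its pixels and a Poisson uncertainty
#' \eqn{\sqrt{\sum c}/n_{pix}}. Empty bins are dropped. The conservation
#' identity \eqn{\sum_b \bar{c}_b n_b = \sum c} holds exactly.
#'
#' @param frame A `detector_frame`.
#' @param geom A `detector_geometry` (shape must match the frame).
#' @param n_bins Number of angular bins (default 2000, oversampling the
#'   narrowest peaks the pipeline simulates by several points).
#' @param axis_kind Output axis, 2-theta degrees or s in 1/A.
#' @param two_theta_range Optional length-2 clip of the angular range;
#'   defaults to the full unmasked pixel range.
#' @return An `xrd_pattern` whose meta records bin pixel counts (`n_pix`).
#' @export
azimuthal_integrate <- function(frame, geom, n_bins = 2000,
                                axis_kind = c("two_theta_deg", "s_inv_angstrom"),
                                two_theta_range = NULL) {
  axis_kind <- match.arg(axis_kind)
  stopifnot(inherits(frame, "detector_frame"), inherits(geom, "detector_geometry"))
  if (n_bins < 2) stop("n_bins must be at least 2", call. = FALSE)
  if (geom$n_rows != nrow(frame$counts) || geom$n_cols != ncol(frame$counts)) {
    stop("geometry and frame dimensions differ", call. = FALSE)
  }
  tt <- .pixel_two_theta(geom)
  ok <- !frame$mask
  if (!any(ok)) stop("all pixels are masked", call. = FALSE)
  tt_ok <- tt[ok]; c_ok <- frame$counts[ok]
  rng <- if (is.null(two_theta_range)) range(tt_ok) else sort(two_theta_range)
  inside <- tt_ok >= rng[1] & tt_ok <= rng[2]
  tt_ok <- tt_ok[inside]; c_ok <- c_ok[inside]
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(tt_ok, edges, rightmost.closed = TRUE, all.inside = TRUE)
  n_pix <- tabulate(bin, nbins = n_bins)
  tot <- as.numeric(rowsum(c_ok, bin, reorder = TRUE))
  bins_used <- sort(unique(bin))
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  mean_c <- tot / n_pix[bins_used]
  sig <- sqrt(pmax(tot, 1)) / n_pix[bins_used]
  axis <- centers[bins_used]
  if (axis_kind == "s_inv_angstrom") axis <- s_from_two_theta(axis, geom$wavelength)
  pattern1d(axis, mean_c, sig, axis_kind = axis_kind,
            meta = list(n_pix = n_pix[bins_used], exposure = frame$exposure,
                        wavelength = geom$wavelength, distance_mm = geom$distance))
}

#' Detector frame and geometry file I/O
#'
#' Frames are stored as 16-bit unsigned-integer grayscale TIFF images with a
#' plain-text sidecar geometry file of `key value` lines
#' (`distance_mm`, `pixel_size_mm`, `beam_center_row`, `beam_center_col`,
#' `wavelength_A`). Masked pixels are not representable in the TIFF; a mask
#' may be supplied on read.
#'
#' @param frame A `detector_frame` (counts are clipped at 65535).
#' @param path TIFF file path; the geometry sidecar uses `paste0(path, ".geom")`.
#' @param geom A `detector_geometry`.
#' @return Reading returns a list `(frame, geom)`; writing returns `path`
#'   invisibly.
#' @export
write_frame_tiff <- function(frame, geom, path) {
  stopifnot(inherits(frame, "detector_frame"), inherits(geom, "detector_geometry"))
  img <- pmin(frame$counts, 65535) / 65535
  tiff::writeTIFF(img, path, bits.per.sample = 16, compression = "none")
  geo <- c(
    distance_mm = geom$distance, pixel_size_mm = geom$pixel_size,
    beam_center_row = geom$beam_center[1], beam_center_col = geom$beam_center[2],
    wavelength_A = geom$wavelength, exposure_s = frame$exposure
  )
  writeLines(sprintf("%s %.10g", names(geo), geo), paste0(path, ".geom"))
  invisible(path)
}

#' @rdname write_frame_tiff
#' @param mask Optional logical mask applied to the frame on read.
#' @export
read_frame_tiff <- function(path, mask = NULL) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  counts <- round(as.matrix(img))
  geo_lines <- readLines(paste0(path, ".geom"))
  kv <- do.call(rbind, strsplit(trimws(geo_lines), "\\s+"))
  geo <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  geom <- detector_geometry(
    distance = geo[["distance_mm"]], pixel_size = geo[["pixel_size_mm"]],
    beam_center = c(geo[["beam_center_row"]], geo[["beam_center_col"]]),
    wavelength = geo[["wavelength_A"]],
    n_rows = nrow(counts), n_cols = ncol(counts)
  )
  exposure <- if ("exposure_s" %in% names(geo)) geo[["exposure_s"]] else 1
  list(frame = detector_frame(counts, mask = mask, exposure = exposure),
       geom = geom)
}
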