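#' Baseline estimation under Bragg peaks
#'
#' Iterative smoothing-and-clipping baseline: the current estimate is
#' smoothed with a centred rolling mean and replaced by the pointwise minimum
#' of itself and the smoothed curve, which progressively erodes narrow
#' upward excursions (Bragg peaks) while following the smooth cellular
#' scattering decay. A final light smoothing pass removes clip artefacts.
#'
#' @param p An `xrd_pattern`.
#' @param half_window Half width of the rolling window in points (>= 2);
#'   should exceed the widest peak's half width in points.
#' @param n_iter Number of clip iterations.
#' @return Numeric baseline, same length as the pattern.
#' @export
estimate_baseline <- function(p, half_window = 50, n_iter = 40) {
  .assert_pattern(p)
  if (half_window < 2) stop("half_window must be at least 2", call. = FALSE)
  n <- nrow(p)
  if (n < 2 * half_window + 1) {
    stop("profile shorter than the baseline window", call. = FALSE)
  }
  b <- p$intensity
  for (i in seq_len(n_iter)) {
    b <- pmin(b, .roll_mean(b, half_window))
  }
  b <- pmin(p$intensity, .roll_mean(b, max(2, floor(half_window / 2))))
  # the min-clip rides the lower noise envelope on noisy input; re-centre on
  # the median residual (zero for peak-free smooth profiles, robust to
  # sparse peaks) so residuals are unbiased for significance testing
  b + stats::median(p$intensity - b)
}

# centred rolling mean; windows shrink symmetrically at the edges so a
# convex decay is never pulled down at the profile ends
.roll_mean <- function(x, hw) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  hw_i <- pmin(hw, seq_len(n) - 1, n - seq_len(n))
  lo <- seq_len(n) - hw_i
  hi <- seq_len(n) + hw_i
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# robust local noise: 1.4826 * MAD of the detrended profile in a sliding
# window (robust to the peaks themselves)
.local_noise <- function(resid, half_window) {
  n <- length(resid)
  idx <- seq_len(n)
  out <- numeric(n)
  # evaluate on a coarse set of anchors and interpolate: O(n * window / stride)
  stride <- max(1, floor(half_window / 2))
  anchors <- unique(c(seq(1, n, by = stride), n))
  vals <- vapply(anchors, function(i) {
    lo <- max(1, i - half_window); hi <- min(n, i + half_window)
    stats::mad(resid[lo:hi])
  }, numeric(1))
  stats::approx(anchors, vals, xout = idx, rule = 2)$y
}

#' Detect Bragg peaks above the cellular background
#'
#' Flags contiguous runs of at least `min_points` points exceeding
#' `baseline + k_sigma * sigma_local` and reports each run as one peak with
#' an intensity-weighted centroid position. The local noise level is, by
#' default, `1.4826 * MAD` of the baseline-subtracted profile in a sliding
#' window (robust against the peaks themselves); with `noise = "sigma"` the
#' pattern's propagated per-point counting sigmas are used instead.
#'
#' @param p An `xrd_pattern`.
#' @param k_sigma Significance threshold in local-noise units.
#' @param min_points Minimum run length in points.
#' @param half_window Window for baseline and noise estimation.
#' @param noise `"mad"` (default) or `"sigma"`.
#' @param baseline Optional precomputed baseline.
#' @return A tibble of peak calls: `position`, `height`, `snr`, `width`,
#'   `n_points`.
#' @export
detect_peaks <- function(p, k_sigma = 5, min_points = 3, half_window = 50,
                         noise = c("mad", "sigma"), baseline = NULL) {
  .assert_pattern(p)
  noise <- match.arg(noise)
  if (k_sigma <= 0) stop("k_sigma must be positive", call. = FALSE)
  if (is.null(baseline)) baseline <- estimate_baseline(p, half_window = half_window)
  resid <- p$intensity - baseline
  sig <- if (noise == "mad") {
    pmax(.local_noise(resid, half_window), 1e-12)
  } else {
    p$sigma
  }
  above <- resid >= k_sigma * sig * (1 - 1e-6)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= min_points
  if (!any(keep)) {
    return(tibble::tibble(position = numeric(), height = numeric(),
                          snr = numeric(), width = numeric(),
                          n_points = integer()))
  }
  rows <- lapply(which(keep), function(i) {
    idx <- starts[i]:ends[i]
    wts <- pmax(resid[idx], 0)
    pos <- sum(p$axis[idx] * wts) / sum(wts)
    apex <- idx[which.max(resid[idx])]
    tibble::tibble(
      position = pos,
      height = resid[apex],
      snr = resid[apex] / sig[apex],
      width = p$axis[ends[i]] - p$axis[starts[i]] +
        stats::median(diff(p$axis)),
      n_points = length(idx)
    )
  })
  dplyr::bind_rows(rows)
}

#' Decide whether a profile contains crystalline material
#'
#' The screening call of the pipeline: a sample is scored crystal-positive
#' when at least `min_peaks` significant Bragg peaks (snr >= `k_sigma`) stand
#' above the cellular background, optionally after subtracting a reference
#' (mock/buffer) profile on the same grid. A single excursion is deliberately
#' not accepted as proof of crystallinity by default.
#'
#' @param sample An `xrd_pattern`.
#' @param reference Optional `xrd_pattern` on the identical grid subtracted
#'   before peak detection.
#' @param k_sigma Peak significance threshold (default 5).
#' @param min_peaks Minimum number of significant peaks (default 2).
#' @param min_points,half_window,noise Passed to [detect_peaks()].
#' @param detect_k_sigma Run threshold used for candidate detection before
#'   the snr filter (defaults to `k_sigma`).
#' @return A list of class `screening_result`: `peaks` (tibble),
#'   `crystal_present`, `score` (max snr, 0 when no peaks), `baseline`.
#' @export
classify_crystal_content <- function(sample, reference = NULL, k_sigma = 5,
                                     min_peaks = 2, min_points = 3,
                                     half_window = 50,
                                     noise = c("mad", "sigma"),
                                     detect_k_sigma = k_sigma) {
  noise <- match.arg(noise)
  p <- if (!is.null(reference)) subtract_buffer(sample, reference) else sample
  baseline <- estimate_baseline(p, half_window = half_window)
  peaks <- detect_peaks(p, k_sigma = detect_k_sigma, min_points = min_points,
                        half_window = half_window, noise = noise,
                        baseline = baseline)
  sig <- peaks[peaks$snr >= k_sigma * (1 - 1e-6), , drop = FALSE]
  structure(
    list(peaks = peaks,
         crystal_present = nrow(sig) >= min_peaks,
         score = if (nrow(peaks)) max(peaks$snr) else 0,
         n_significant = nrow(sig),
         baseline = baseline,
         k_sigma = k_sigma, min_peaks = min_peaks),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> crystal_present: %s  (%d significant peaks, max snr %.1f)\n",
              x$crystal_present, x$n_significant, x$score))
  invisible(x)
}

#' Tidy a screening result
#'
#' @param x A `screening_result`.
#' @param ... Unused.
#' @return The peak tibble with the sample-level call attached as columns.
#' @export
tidy.screening_result <- function(x, ...) {
  pk <- x$peaks
  pk$crystal_present <- x$crystal_present
  pk
}

#' @rdname tidy.screening_result
#' @export
glance.screening_result <- function(x, ...) {
  tibble::tibble(crystal_present = x$crystal_present, score = x$score,
                 n_peaks = nrow(x$peaks), n_significant = x$n_significant,
                 k_sigma = x$k_sigma, min_peaks = x$min_peaks)
}
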