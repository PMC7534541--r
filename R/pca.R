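#' PCA phase clustering of powder profiles
#'
#' Groups scattering profiles by crystalline phase: each pattern is
#' restricted to an angular window (default 0.4–2.0 degrees 2-theta, the
#' fingerprint region), resampled onto a common grid by linear interpolation
#' where needed, normalised to unit total intensity (so the clustering
#' responds to peak positions — the phase — rather than to crystal-fraction
#' amplitude differences), mean-centred across patterns and decomposed into
#' principal components. Agglomerative clustering (average linkage,
#' Euclidean distance in PC space) cut at `k` groups yields the phase labels.
#'
#' @param patterns List of `xrd_pattern`s on the 2-theta axis.
#' @param window Length-2 angular window in degrees (default `c(0.4, 2.0)`).
#' @param n_components Number of PC axes used for clustering (default 3).
#' @param k Number of clusters; user-supplied by design (set `k = NULL` with
#'   `auto_k = TRUE` for a silhouette-based choice over `2:k_max`).
#' @param auto_k,k_max Optional silhouette-based selection of `k`.
#' @return A list of class `phase_clustering`: `scores` (tibble sample ×
#'   PC coordinates with `label`), `explained_variance` (fractions,
#'   non-increasing), `labels` (integer vector), `window`, `hclust`.
#' @examples
#' # see the package vignette for a four-phase worked example
#' @export
pca_cluster <- function(patterns, window = c(0.4, 2.0), n_components = 3,
                        k = NULL, auto_k = FALSE, k_max = 8) {
  if (!length(patterns)) stop("no patterns supplied", call. = FALSE)
  lapply(patterns, .assert_pattern)
  kinds <- vapply(patterns, axis_kind, character(1))
  if (!all(kinds == "two_theta_deg")) {
    stop("all patterns must be on the two-theta axis", call. = FALSE)
  }
  if (is.null(k) && !auto_k) stop("supply k or set auto_k = TRUE", call. = FALSE)
  if (!is.null(k) && k > length(patterns)) {
    stop("k exceeds the number of patterns", call. = FALSE)
  }
  window <- sort(window)
  # common grid: the first pattern's points inside the window
  ref_axis <- patterns[[1]]$axis
  grid <- ref_axis[ref_axis >= window[1] & ref_axis <= window[2]]
  if (length(grid) < 4) stop("window contains too few points", call. = FALSE)
  mat <- t(vapply(patterns, function(p) {
    stats::approx(p$axis, p$intensity, xout = grid, rule = 2)$y
  }, numeric(length(grid))))
  tot <- rowSums(abs(mat))
  if (any(tot == 0)) stop("a pattern has zero total intensity in the window", call. = FALSE)
  mat <- mat / tot
  centred <- scale(mat, center = TRUE, scale = FALSE)
  if (max(abs(centred)) < 1e-14) {
    stop("degenerate input: all patterns are identical in the window", call. = FALSE)
  }
  n_components <- min(n_components, nrow(mat) - 1, ncol(mat))
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  hc <- stats::hclust(stats::dist(scores), method = "average")
  if (is.null(k)) {
    sil <- vapply(2:min(k_max, length(patterns) - 1), function(kk) {
      .mean_silhouette(scores, stats::cutree(hc, kk))
    }, numeric(1))
    k <- (2:min(k_max, length(patterns) - 1))[which.max(sil)]
  }
  labels <- .canonical_labels(stats::cutree(hc, k))
  ids <- names(patterns)
  if (is.null(ids)) ids <- sprintf("pattern%02d", seq_along(patterns))
  sc <- tibble::as_tibble(scores, .name_repair = "minimal")
  names(sc) <- paste0("PC", seq_len(ncol(sc)))
  sc <- dplyr::bind_cols(tibble::tibble(sample = ids), sc,
                         tibble::tibble(label = labels))
  structure(
    list(scores = sc, explained_variance = ev[seq_len(n_components)],
         labels = labels, window = window, k = k, hclust = hc),
    class = "phase_clustering"
  )
}

# relabel clusters by first appearance so labels are input-order canonical
.canonical_labels <- function(raw) {
  first <- match(unique(raw), raw)
  map <- order(first)
  out <- match(raw, unique(raw))
  out
}

.mean_silhouette <- function(scores, labels) {
  d <- as.matrix(stats::dist(scores))
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(n) != i]) else 0
    bs <- vapply(setdiff(unique(labels), labels[i]),
                 function(l) mean(d[i, labels == l]), numeric(1))
    if (!length(bs)) return(0)
    b <- min(bs)
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' @export
print.phase_clustering <- function(x, ...) {
  cat(sprintf("<phase_clustering> %d patterns, %d clusters in (%g, %g) deg window\n",
              nrow(x$scores), x$k, x$window[1], x$window[2]))
  cat("  explained variance:", paste(sprintf("%.1f%%", 100 * x$explained_variance),
                                     collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.phase_clustering <- function(x, ...) x$scores

#' @export
glance.phase_clustering <- function(x, ...) {
  tibble::tibble(k = x$k, n_patterns = nrow(x$scores),
                 pc1_var = x$explained_variance[1],
                 silhouette = .mean_silhouette(
                   as.matrix(x$scores[grep("^PC", names(x$scores))]), x$labels))
}

#' @export
autoplot.phase_clustering <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = factor(.data$label))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(colour = "phase",
                  x = sprintf("PC1 (%.0f%%)", 100 * object$explained_variance[1]),
                  y = sprintf("PC2 (%.0f%%)", 100 * object$explained_variance[2])) +
    ggplot2::theme_minimal()
}

#' Export PCA scores as tab-separated text
#'
#' @param clustering A `phase_clustering`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pca_scores <- function(clustering, path) {
  utils::write.table(as.data.frame(clustering$scores), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
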