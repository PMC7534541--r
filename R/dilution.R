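#' Detection limit from a dilution series
#'
#' Screens every step of a 1:2 dilution series and reports the crystal-cell
#' fraction at the last step that is still scored crystal-positive — the
#' operational detection limit of the setup for that phase. Max-SNR scores
#' are checked for monotone decrease with dilution (they should fall as the
#' number of crystals in the irradiated volume halves) and any violation is
#' reported, not hidden.
#'
#' @param series A `dilution_series` from [make_dilution_series()], or any
#'   list with a `steps` tibble of the same shape.
#' @param ... Passed to [classify_crystal_content()] (e.g. `k_sigma`,
#'   `min_peaks`, `noise`).
#' @param use_reference Subtract each step's buffer profile before screening
#'   (default TRUE).
#' @return A list of class `detection_limit`: `limit_fraction` (NA with
#'   `note = "above first-step fraction"` when no step is positive),
#'   `last_positive_step`, `per_step` (tibble: step, fraction, score,
#'   n_significant, crystal_present), `monotone_scores`, `results` (list of
#'   `screening_result`).
#' @export
detection_limit <- function(series, ..., use_reference = TRUE) {
  steps <- series$steps
  if (is.null(steps) || nrow(steps) < 2) {
    stop("a dilution series needs at least 2 steps", call. = FALSE)
  }
  results <- purrr::map(seq_len(nrow(steps)), function(i) {
    ref <- if (use_reference) steps$buffer[[i]] else NULL
    classify_crystal_content(steps$sample[[i]], reference = ref, ...)
  })
  per_step <- tibble::tibble(
    step = steps$step,
    dilution_factor = steps$dilution_factor,
    fraction = steps$fraction,
    score = vapply(results, `[[`, numeric(1), "score"),
    n_significant = vapply(results, `[[`, numeric(1), "n_significant"),
    crystal_present = vapply(results, `[[`, logical(1), "crystal_present")
  )
  pos <- which(per_step$crystal_present)
  if (!length(pos)) {
    limit <- NA_real_
    last_pos <- NA_integer_
    note <- "above first-step fraction"
  } else {
    last_pos <- per_step$step[max(pos)]
    limit <- per_step$fraction[max(pos)]
    note <- NULL
  }
  structure(
    list(limit_fraction = limit, last_positive_step = last_pos,
         per_step = per_step,
         monotone_scores = !is.unsorted(rev(per_step$score)),
         note = note, results = results),
    class = "detection_limit"
  )
}

#' @export
print.detection_limit <- function(x, ...) {
  if (is.na(x$limit_fraction)) {
    cat("<detection_limit> no positive step (", x$note, ")\n")
  } else {
    cat(sprintf("<detection_limit> last positive step %d -> fraction %.4g (%.2f%% of cells)\n",
                x$last_positive_step, x$limit_fraction, 100 * x$limit_fraction))
  }
  print(as.data.frame(x$per_step), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.detection_limit <- function(x, ...) x$per_step

#' @export
glance.detection_limit <- function(x, ...) {
  tibble::tibble(limit_fraction = x$limit_fraction,
                 last_positive_step = x$last_positive_step,
                 monotone_scores = x$monotone_scores,
                 n_steps = nrow(x$per_step))
}

#' @export
autoplot.detection_limit <- function(object, ...) {
  ggplot2::ggplot(object$per_step,
                  ggplot2::aes(x = factor(.data$dilution_factor), y = .data$score,
                               fill = .data$crystal_present)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$results[[1]]$k_sigma,
                        linetype = "dashed") +
    ggplot2::labs(x = "dilution factor", y = "max peak SNR",
                  fill = "crystal present") +
    ggplot2::theme_minimal()
}
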