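#' Plot an extracted ion chromatogram
#'
#' @param object An `eic` tibble.
#' @param ... Unused.
#' @return A ggplot of intensity vs retention time.
#' @export
autoplot.eic <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rt, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      x = "retention time (s)", y = "intensity (counts)",
      title = sprintf("EIC m/z %.4f (+/- %g ppm)",
                      attr(object, "target_mz"), attr(object, "tol_ppm"))) +
    ggplot2::theme_minimal()
}

#' Plot the dynamic-range coverage of a benchmark
#'
#' Shows the distribution of accepted peak heights (log10) split into MAITs
#' and LAITs, visualizing how much dynamic range the lower-abundance
#' isotopologues add.
#'
#' @param object A `benchmark`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.benchmark <- function(object, ...) {
  acc <- tibble::as_tibble(object[object$status != "rejected", ])
  acc$kind <- ifelse(acc$status == "accepted_mait", "MAIT", "LAIT")
  ggplot2::ggplot(acc, ggplot2::aes(x = log10(.data$height),
                                    fill = .data$kind)) +
    ggplot2::geom_histogram(bins = 30, position = "stack") +
    ggplot2::labs(x = "log10 peak height", y = "benchmark peaks",
                  fill = NULL, title = "Benchmark dynamic-range coverage") +
    ggplot2::theme_minimal()
}

#' Plot an assessment report
#'
#' Point estimates with bootstrap confidence intervals for every metric.
#'
#' @param object An `assessment_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assessment_report <- function(object, ...) {
  m <- object$metrics[!is.na(object$metrics$value), ]
  ggplot2::ggplot(m, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper)) +
    ggplot2::coord_flip(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "percent of benchmark peaks",
                  title = "Feature detection assessment",
                  subtitle = sprintf("bootstrap CI, level %.2f, R = %d",
                                     object$settings$level,
                                     object$settings$R)) +
    ggplot2::theme_minimal()
}

#' Tidy a benchmark into a plain tibble
#'
#' @param x A `benchmark`.
#' @param ... Unused.
#' @return The benchmark rows as a plain tibble.
#' @export
tidy.benchmark <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a benchmark
#'
#' @param x A `benchmark`.
#' @param ... Unused.
#' @return A one-row tibble with peak counts, molecule count and dynamic
#'   range.
#' @export
glance.benchmark <- function(x, ...) {
  acc <- x[x$status != "rejected", ]
  tibble::tibble(
    n_peaks = nrow(x),
    n_accepted = nrow(acc),
    n_mait = sum(x$status == "accepted_mait"),
    n_lait = sum(x$status == "accepted_lait"),
    n_rejected = sum(x$status == "rejected"),
    n_molecules = length(unique(x$molecule_id)),
    log10_dynamic_range = if (nrow(acc)) log10(max(acc$height) / min(acc$height))
                          else NA_real_
  )
}
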