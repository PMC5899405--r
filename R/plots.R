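#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a normalised windowed frequency track
#'
#' One panel per chromosome, normalised frequency (0-1) against window
#' midpoint in Mb — the genome-wide representation used to judge how
#' informative positions distribute along chromosomes.
#'
#' @param object A [window_frequencies()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot capmeth_windows
#' @export
autoplot.capmeth_windows <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$window_start + attr_window(df)) / 1e6,
    y = .data$normalized
  )) +
    ggplot2::geom_col(width = attr_window(df) / 1e6, fill = "grey25") +
    ggplot2::facet_wrap(~chromosome, ncol = 1, strip.position = "right") +
    ggplot2::labs(x = "position (Mb)", y = "normalised frequency") +
    ggplot2::theme_minimal()
}

attr_window <- function(df) {
  ws <- sort(unique(diff(sort(unique(df$window_start)))))
  if (length(ws) == 0) 1e6 else ws[1] / 2
}

#' Volcano-style view of differential methylation results
#'
#' Methylation difference (percentage points) against `-log10(p)`;
#' significant sites highlighted.
#'
#' @param object A [differential_methylation()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot capmeth_dm
#' @export
autoplot.capmeth_dm <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- attr(object, "params")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$meth_difference,
    y = -log10(pmax(.data$p_value, 1e-300)),
    colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(p$alpha), linetype = 2) +
    ggplot2::geom_vline(
      xintercept = c(-p$min_diff, p$min_diff), linetype = 2
    ) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick")
    ) +
    ggplot2::labs(
      x = "methylation difference (pp)", y = expression(-log[10](p))
    ) +
    ggplot2::theme_minimal()
}

#' Per-contig capture coverage plot
#'
#' @param report A [coverage_stats()] result.
#' @return A ggplot of per-contig percent covered against mean depth.
#' @export
plot_coverage <- function(report) {
  stopifnot(inherits(report, "coverage_report"))
  ggplot2::ggplot(report$per_contig, ggplot2::aes(
    x = .data$mean_depth, y = .data$pct_covered
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean depth (x)", y = "% of contig covered") +
    ggplot2::theme_minimal()
}
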