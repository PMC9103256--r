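#' Plot a metagene methylation profile
#'
#' One line per context across the upstream flank, scaled gene body and
#' downstream flank.
#'
#' @param profile tibble from [metagene_profile()].
#' @param flank_bins number of bins per flank (for the segment guides).
#' @param body_bins number of gene-body bins.
#' @return a ggplot object.
#' @export
plot_metagene <- function(profile, flank_bins = 20L, body_bins = 60L) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$bin, y = .data$mean_level,
                               colour = .data$context)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = c(flank_bins + 0.5,
                                       flank_bins + body_bins + 0.5),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_x_continuous(
      breaks = c(1, flank_bins + 0.5, flank_bins + body_bins + 0.5,
                 2 * flank_bins + body_bins),
      labels = c("-flank", "TSS", "TES", "+flank")
    ) +
    ggplot2::labs(x = NULL, y = "methylation level", colour = "context") +
    ggplot2::theme_minimal()
}

#' Plot per-context methylation summaries
#'
#' Bar chart of each context's share of all methylated cytosines.
#'
#' @param summary tibble from [summarize_contexts()] (or several, row-bound
#'   with a `sample_id` column).
#' @return a ggplot object.
#' @export
plot_context_summary <- function(summary) {
  p <- ggplot2::ggplot(summary,
                       ggplot2::aes(x = .data$context, y = .data$mc_share,
                                    fill = .data$context)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "context", y = "share of methylated cytosines") +
    ggplot2::theme_minimal()
  if ("sample_id" %in% names(summary)) {
    p <- p + ggplot2::facet_wrap(~sample_id)
  }
  p
}

#' Volcano-style plot of tested methylation windows
#'
#' Level difference (percentage points) against `-log10(q)`, with called
#' DMRs highlighted.
#'
#' @param object a `dmr_result` from [call_dmrs()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dmr_result <- function(object, ...) {
  w <- object$windows %>%
    mutate(delta = (.data$level_a - .data$level_b) * 100)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$delta,
                                  y = -log10(pmax(.data$q, 1e-300)))) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_point(
      data = object$dmrs,
      mapping = ggplot2::aes(colour = .data$direction),
      size = 1.2
    ) +
    ggplot2::facet_wrap(~context) +
    ggplot2::labs(x = "methylation difference (percentage points)",
                  y = "-log10(q)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
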