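#' Volcano plot of a gene fitness analysis
#'
#' Mean log2(50C/37C) against -log10(FDR), hits highlighted, with the
#' effect-size and FDR thresholds drawn as dashed lines.
#'
#' @param object A `gene_fitness` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gene_fitness <- function(object, ...) {
  v <- volcano_table(object)
  p <- object$params
  ggplot2::ggplot(v, ggplot2::aes(
    x = .data$mean_log2fc, y = .data$neg_log10_fdr, colour = .data$is_hit
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(
      xintercept = c(-1, 1) * p$lfc_threshold, linetype = "dashed"
    ) +
    ggplot2::geom_hline(
      yintercept = -log10(p$fdr_threshold), linetype = "dashed"
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey40"),
      name = "hit"
    ) +
    ggplot2::labs(
      x = expression(log[2] * "(50" * degree * "C / 37" * degree * "C)"),
      y = expression(-log[10] * "(FDR)")
    ) +
    ggplot2::theme_minimal()
}

#' Insertion density along the genome
#'
#' Bar chart of insertions per bin (default 50 kb), faceted by chromosome.
#'
#' @param density A density table from [bin_density()].
#' @return A ggplot.
#' @export
plot_insertion_density <- function(density) {
  ggplot2::ggplot(density, ggplot2::aes(
    x = (.data$bin_start + .data$bin_end) / 2e3, y = .data$insertion_count
  )) +
    ggplot2::geom_col(width = (density$bin_end[1] - density$bin_start[1]) / 1e3) +
    ggplot2::facet_wrap(~chromosome, scales = "free_x") +
    ggplot2::labs(x = "position (kb)", y = "insertions per bin") +
    ggplot2::theme_minimal()
}

#' Replicate concordance scatter plot
#'
#' Normalized abundances of one replicate against another on log10 axes,
#' annotated with the OLS R^2.
#'
#' @param counts A normalized [bc_counts] table.
#' @param sample_a,sample_b Sample ids to compare.
#' @return A ggplot.
#' @export
plot_replicate_concordance <- function(counts, sample_a, sample_b) {
  stopifnot(inherits(counts, "bc_counts"))
  df <- tibble::tibble(a = counts[[sample_a]], b = counts[[sample_b]])
  r2 <- stats::cor(df$a, df$b)^2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = sample_a, y = sample_b,
      subtitle = sprintf("R² = %.4f", r2)
    ) +
    ggplot2::theme_minimal()
}
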