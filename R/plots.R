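# ggplot2 displays for the main result types.

#' Plot a coverage trace
#'
#' Sense coverage is drawn upward and antisense downward, the usual display
#' for strand-resolved small-RNA tracks; optional cut-site and exon guides.
#'
#' @param object A `coverage_trace` from [build_coverage()].
#' @param cut Optional [cut_site()] drawn as a vertical line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_trace <- function(object, cut = NULL, ...) {
  g <- attr(object, "gene")
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("pos", "rpm_sense", "rpm_antisense")],
    cols = c("rpm_sense", "rpm_antisense"),
    names_to = "strand", values_to = "rpm"
  )
  df$rpm[df$strand == "rpm_antisense"] <- -df$rpm[df$strand == "rpm_antisense"]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$rpm,
                                        fill = .data$strand)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(
      values = c(rpm_sense = "#2c7fb8", rpm_antisense = "#d95f0e"),
      labels = c(rpm_sense = "sense", rpm_antisense = "antisense"),
      name = NULL
    ) +
    ggplot2::labs(x = sprintf("%s position (0-based)", g$chrom),
                  y = "coverage (RPM)", title = g$gene_id) +
    ggplot2::theme_minimal()
  if (!is.null(cut)) {
    p <- p + ggplot2::geom_vline(xintercept = cut$cut_position,
                                 linetype = "dashed", colour = "grey30")
  }
  p
}

#' Plot screen scores: RLuc vs FLuc with the fitted curve, or z by gene
#'
#' @param object A `screen_scores` tibble from [score_wells()].
#' @param type `"fit"` (normalized RLuc against FLuc with the LOESS curve) or
#'   `"z"` (ranked z-scores with the candidate thresholds).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_scores <- function(object, type = c("fit", "z"), ...) {
  type <- match.arg(type)
  thr <- attr(object, "thresholds")
  df <- as_tibble(object)
  if (type == "fit") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$fluc_norm, y = .data$rluc_norm,
                                     colour = .data$annotation)) +
      ggplot2::geom_point(size = 0.8, alpha = 0.6) +
      ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "black") +
      ggplot2::labs(x = "normalized FLuc (log)", y = "normalized RLuc (log)") +
      ggplot2::theme_minimal()
  } else {
    df <- arrange(df, .data$z)
    df$rank <- seq_len(nrow(df))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$z,
                                     colour = .data$annotation)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::geom_hline(yintercept = c(thr$lower, thr$upper),
                          linetype = "dashed", colour = "grey30") +
      ggplot2::labs(x = "well rank", y = "LOESS-residual z-score") +
      ggplot2::theme_minimal()
  }
}

#' Bar plot of size-normalized feature coverage across replicates
#'
#' @param fc Long tibble of [count_feature_reads()] rows over replicates.
#' @return A ggplot object.
#' @export
plot_feature_coverage <- function(fc) {
  ggplot2::ggplot(
    filter(fc, .data$axis == "genomic"),
    ggplot2::aes(x = .data$feature, y = .data$normalized_coverage)
  ) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$replicate_id), size = 1.5) +
    ggplot2::labs(x = NULL, y = "RPM per unit feature size") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
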