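# ggplot2 views of the main result types: ranked activity with strength
# thresholds, replicate concordance, YY1 dosage and group-wise expression.

#' Plot ranked enhancer activities with strength thresholds
#'
#' @param activity_log2 Numeric vector of log2 activities.
#' @param thresholds Optional `strength_thresholds`; drawn as dashed lines.
#' @return A ggplot object.
#' @export
plot_ranked_activity <- function(activity_log2, thresholds = NULL) {
  df <- tibble(rank = seq_along(activity_log2),
               activity_log2 = sort(activity_log2))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$activity_log2)) +
    ggplot2::geom_point(size = 0.6, colour = "#2c7fb8") +
    ggplot2::labs(x = "Enhancer rank", y = "STARR-seq activity (log2)") +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    p <- p + ggplot2::geom_hline(
      yintercept = c(thresholds$weak_upper_log2,
                     thresholds$strong_lower_log2),
      linetype = "dashed", colour = "grey30")
  }
  p
}

#' Plot replicate concordance of binned coverage
#'
#' Scatter of per-bin RPM for two replicates with the squared Pearson
#' correlation in the subtitle.
#'
#' @inheritParams replicate_correlation
#' @return A ggplot object.
#' @export
plot_replicate_correlation <- function(frags_a, frags_b, sizes,
                                       bin_bp = 500L) {
  bins <- genome_bins(sizes, bin_bp)
  ka <- count_fragments(frags_a, bins, chromosomes = names(sizes))$count
  kb <- count_fragments(frags_b, bins, chromosomes = names(sizes))$count
  keep <- ka > 0 | kb > 0
  df <- tibble(rpm_a = ka[keep] * 1e6 / nrow(frags_a),
               rpm_b = kb[keep] * 1e6 / nrow(frags_b))
  r2 <- stats::cor(df$rpm_a, df$rpm_b)^2
  ggplot2::ggplot(df, ggplot2::aes(.data$rpm_a, .data$rpm_b)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Replicate 1 (RPM)", y = "Replicate 2 (RPM)",
                  subtitle = sprintf("R² = %.3f over %d bins",
                                     r2, nrow(df))) +
    ggplot2::theme_minimal()
}

#' @describeIn yy1_dosage Boxplot of activity by YY1 motif-count bin.
#' @param object A `yy1_dosage` object.
#' @param ... Unused.
#' @export
autoplot.yy1_dosage <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$bin, .data$activity_log2)) +
    ggplot2::geom_boxplot(fill = "#a6bddb", outlier.size = 0.5) +
    ggplot2::labs(x = "YY1 motifs per enhancer",
                  y = "STARR-seq activity (log2)",
                  subtitle = sprintf("trend %.2f log2/motif; ANOVA p = %.2g",
                                     object$slope, object$anova_p)) +
    ggplot2::theme_minimal()
}

#' @describeIn expression_by_group Boxplot of log TPM by group.
#' @param object An `expression_comparison` object.
#' @param ... Unused.
#' @export
autoplot.expression_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$group, .data$log_tpm)) +
    ggplot2::geom_boxplot(fill = "#c7e9c0", outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "Expression (log2 TPM + 1)",
                  subtitle = sprintf("one-way ANOVA p = %.2g",
                                     object$anova_p)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
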