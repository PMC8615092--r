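#' Plot methods for pathrepro results
#'
#' `autoplot.saturation_result()` draws the detection saturation curve
#' (boxplots of detected-feature counts per combination size);
#' `autoplot.repro_result()` the per-size distribution of pairwise
#' Spearman correlations between pathway-score vectors;
#' `autoplot.cv_report()` the per-gene CV distribution; and
#' `autoplot.rank_agreement()` the mean-rank scatter with
#' platform-exclusive genes visible as marginal spurs.
#'
#' @param object A pathrepro result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name pathrepro_plots
NULL

#' @rdname pathrepro_plots
#' @method autoplot saturation_result
#' @export
autoplot.saturation_result <- function(object, ...) {
  ggplot2::ggplot(object$combinations,
                  ggplot2::aes(x = factor(.data$k), y = .data$n_detected)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = "Number of replicates",
                  y = sprintf("Detected %ss", object$level),
                  title = "Detection saturation over replicate combinations") +
    ggplot2::theme_minimal()
}

#' @rdname pathrepro_plots
#' @method autoplot repro_result
#' @export
autoplot.repro_result <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = factor(.data$k), y = .data$rho)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = "Number of replicates",
                  y = "Pairwise Spearman correlation of pathway scores",
                  title = sprintf("Pathway-score reproducibility (%s)",
                                  object$method)) +
    ggplot2::theme_minimal()
}

#' @rdname pathrepro_plots
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$per_gene, ggplot2::aes(x = .data$cv)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$median_cv, linetype = 2) +
    ggplot2::labs(x = "Per-gene CV (%)", y = "Genes",
                  title = sprintf("Median CV = %.1f%%", object$median_cv)) +
    ggplot2::theme_minimal()
}

#' @rdname pathrepro_plots
#' @method autoplot rank_agreement
#' @export
autoplot.rank_agreement <- function(object, ...) {
  ggplot2::ggplot(object$mean_ranks,
                  ggplot2::aes(x = .data$mean_rank_a, y = .data$mean_rank_b)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::labs(x = "Mean gene rank (platform A)",
                  y = "Mean gene rank (platform B)",
                  title = sprintf("Mean-rank agreement, Pearson R = %.3f",
                                  object$pearson)) +
    ggplot2::theme_minimal()
}
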