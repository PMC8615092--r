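#' Broom-style tidiers for pathrepro result objects
#'
#' `tidy()` returns the per-unit records (per gene, per combination, or
#' per combination pair); `glance()` returns a one-row overview.
#'
#' @param x A `cv_report`, `rank_agreement`, `saturation_result` or
#'   `repro_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name pathrepro_tidiers
NULL

#' @rdname pathrepro_tidiers
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$per_gene

#' @rdname pathrepro_tidiers
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble(median_cv = x$median_cv, n_genes_used = x$n_genes_used,
         n_replicates = x$n_replicates, platform = x$platform)
}

#' @rdname pathrepro_tidiers
#' @method tidy rank_agreement
#' @export
tidy.rank_agreement <- function(x, ...) x$mean_ranks

#' @rdname pathrepro_tidiers
#' @method glance rank_agreement
#' @export
glance.rank_agreement <- function(x, ...) {
  tibble(pearson = x$pearson, n_genes_used = x$n_genes_used,
         n_exclusive_a = length(x$exclusive_a),
         n_exclusive_b = length(x$exclusive_b),
         include_exclusive = x$include_exclusive)
}

#' @rdname pathrepro_tidiers
#' @method tidy saturation_result
#' @export
tidy.saturation_result <- function(x, ...) x$combinations

#' @rdname pathrepro_tidiers
#' @method glance saturation_result
#' @export
glance.saturation_result <- function(x, ...) {
  full <- x$summary$median[x$summary$k == x$n_replicates]
  tibble(level = x$level, n_replicates = x$n_replicates,
         detection_threshold = x$detection_threshold,
         n_detected_full = full, platform = x$platform)
}

#' @rdname pathrepro_tidiers
#' @method tidy repro_result
#' @export
tidy.repro_result <- function(x, ...) x$pairs

#' @rdname pathrepro_tidiers
#' @method glance repro_result
#' @export
glance.repro_result <- function(x, ...) {
  k1 <- x$summary[x$summary$k == 1L, ]
  tibble(method = x$method, platform = x$platform,
         n_replicates = x$n_replicates, n_pathways = x$n_pathways,
         n_pairs = nrow(x$pairs),
         median_k1 = if (nrow(k1)) k1$median else NA_real_,
         iqr_k1 = if (nrow(k1)) k1$iqr else NA_real_)
}

#' @method print cv_report
#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "Coefficient of variation: %d genes x %d replicates%s\n  median CV = %.2f%%\n",
    x$n_genes_used, x$n_replicates,
    if (is.na(x$platform)) "" else paste0(" (", x$platform, ")"),
    x$median_cv))
  invisible(x)
}

#' @method print rank_agreement
#' @export
print.rank_agreement <- function(x, ...) {
  cat(sprintf(
    "Cross-platform mean-rank agreement\n  Pearson R = %.3f over %d genes\n  exclusive genes: %d (platform A), %d (platform B)\n",
    x$pearson, x$n_genes_used, length(x$exclusive_a), length(x$exclusive_b)))
  invisible(x)
}

#' @method print saturation_result
#' @export
print.saturation_result <- function(x, ...) {
  cat(sprintf("Detection saturation (%s level, threshold %g, %d replicates)\n",
              x$level, x$detection_threshold, x$n_replicates))
  print(x$summary)
  invisible(x)
}

#' @method print repro_result
#' @export
print.repro_result <- function(x, ...) {
  cat(sprintf(
    "Pathway-score reproducibility (%s, %d replicates, %d pathways%s)\n",
    x$method, x$n_replicates, x$n_pathways,
    if (is.na(x$platform)) "" else paste0(", ", x$platform)))
  print(x$summary)
  invisible(x)
}
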