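#' Enumerate replicate combinations
#'
#' All \eqn{\binom{n}{k}} ways to choose `k` of the given replicates, in
#' lexicographic order of member indices — for five replicates and k = 4:
#' (1,2,3,4), (1,2,3,5), (1,2,4,5), (1,3,4,5), (2,3,4,5).
#'
#' @param replicate_ids Character vector of replicate labels.
#' @param k Combination size, between 1 and `length(replicate_ids)`.
#' @return List of character vectors, each a combination of replicate IDs.
#' @export
enumerate_combinations <- function(replicate_ids, k) {
  n <- length(replicate_ids)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n) {
    abort(sprintf("`k` must be between 1 and %d", n))
  }
  combn(replicate_ids, as.integer(k), simplify = FALSE)
}

combo_label <- function(members) paste(members, collapse = "+")

#' Pool replicate expression into one pseudo-sample
#'
#' Element-wise sum (default) of the member replicate columns, emulating
#' the increased sensitivity of a deeper single run; `method = "mean"`
#' divides by the combination size, which leaves every gene rank unchanged
#' but makes a fixed TPM threshold depth-invariant.
#'
#' @param x An expression tibble.
#' @param members Character vector of replicate IDs to pool.
#' @param method `"sum"` (default) or `"mean"`.
#' @return A tibble with columns `gene_id` and `tpm`.
#' @export
pool_expression <- function(x, members, method = c("sum", "mean")) {
  method <- match.arg(method)
  x <- expression_matrix(x)
  missing <- setdiff(members, replicate_ids(x))
  if (length(missing) > 0L) {
    abort(paste0("Unknown replicate ID(s): ", paste(missing, collapse = ", ")))
  }
  m <- expr_values(x)[, members, drop = FALSE]
  v <- rowSums(m)
  if (method == "mean") v <- v / length(members)
  tibble(gene_id = x$gene_id, tpm = unname(v))
}

#' Spearman correlation of two score vectors
#'
#' Pearson correlation of the midranks of the pairwise-complete entries.
#' Returns `NA` when fewer than 3 complete pairs remain or when either
#' vector is constant over them.
#'
#' @param x,y Numeric vectors of equal length; `NA`s dropped pairwise.
#' @return A single correlation coefficient in [-1, 1], or `NA`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

#' Median and interquartile range of a set of values
#'
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7); the IQR is Q3 - Q1. Missing values are
#' dropped first.
#'
#' @param values Numeric vector.
#' @return One-row tibble with columns `median`, `iqr`, `n`.
#' @export
median_iqr <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) abort("No non-missing values to summarize")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble(median = q[2L], iqr = q[3L] - q[1L], n = length(values))
}

#' Detection saturation over replicate combinations
#'
#' For every combination size k = 1..n and every combination of that size,
#' counts the features detected in at least one member replicate (the
#' union rule), then summarizes counts per k by median and IQR. The curve
#' shows how quickly added replicates saturate the detectable
#' transcriptome — the central question for depth-limited platforms.
#'
#' @param x An expression tibble (gene- or transcript-level rows).
#' @param detection_threshold Detection threshold (strict `>`); default 0.
#' @param level Label recorded with the result: `"gene"` or
#'   `"transcript"`.
#' @return An object of class `saturation_result`; [tidy()] gives one row
#'   per combination, [glance()] compact metadata, and the `summary`
#'   element the per-k median/IQR table.
#' @export
saturation_analysis <- function(x, detection_threshold = 0,
                                level = c("gene", "transcript")) {
  level <- match.arg(level)
  x <- expression_matrix(x)
  det <- expr_values(x) > detection_threshold
  reps <- replicate_ids(x)
  rows <- purrr::map_dfr(seq_along(reps), function(k) {
    purrr::map_dfr(enumerate_combinations(reps, k), function(members) {
      tibble(k = k, combination = combo_label(members),
             n_detected = sum(rowSums(det[, members, drop = FALSE]) > 0))
    })
  })
  summary <- rows %>%
    group_by(.data$k) %>%
    summarise(median_iqr(.data$n_detected), .groups = "drop")
  structure(
    list(combinations = rows, summary = summary, level = level,
         detection_threshold = detection_threshold,
         n_replicates = length(reps), platform = expr_platform(x)),
    class = "saturation_result")
}

#' Pathway-score reproducibility over replicate combinations
#'
#' The exhaustive replicate-combination scheme: for each combination size
#' k, every combination of k replicates is pooled into a pseudo-sample
#' (sum by default), low-expression filtered, and scored against the
#' pathway collection; the Spearman correlation of the pathway-score
#' vectors is then computed for every unordered pair of distinct size-k
#' combinations, giving \eqn{\binom{\binom{n}{k}}{2}} coefficients per k,
#' summarized as median and IQR. High medians at small k mean single (or
#' few) replicates already give stable pathway calls.
#'
#' Pairs deliberately include overlapping combinations (for example
#' (1,2,3,4) vs (1,2,3,5)), which inflates correlations at large k;
#' `disjoint_only = TRUE` restricts to member-disjoint pairs as a
#' sensitivity check (only meaningful for k <= n/2). The TPM filter is
#' applied to the pooled vector; with `pool = "mean"` the threshold
#' becomes independent of combination size.
#'
#' @inheritParams score_pathways
#' @param expr_threshold Low-expression cutoff applied to each pooled
#'   vector; default 0.1 TPM.
#' @param pool `"sum"` (default) or `"mean"`.
#' @param max_k Largest combination size analyzed; default all (n).
#' @param disjoint_only Only pair combinations with no shared members
#'   (default `FALSE`).
#' @return An object of class `repro_result`; [tidy()] gives one row per
#'   combination pair, [glance()] a one-row overview, and the `summary`
#'   element the per-k median/IQR table.
#' @export
reproducibility_analysis <- function(x, collection,
                                     method = c("singscore", "ssgsea"),
                                     expr_threshold = 0.1,
                                     pool = c("sum", "mean"),
                                     alpha = 0.25, max_k = NULL,
                                     disjoint_only = FALSE) {
  method <- match.arg(method)
  pool <- match.arg(pool)
  check_collection(collection)
  x <- expression_matrix(x)
  m <- expr_values(x)
  reps <- replicate_ids(x)
  if (length(reps) < 2L) abort("Need at least 2 replicates")
  ks <- seq_len(if (is.null(max_k)) length(reps) else
    min(max_k, length(reps)))

  pairs <- purrr::map_dfr(ks, function(k) {
    combos <- enumerate_combinations(reps, k)
    scores <- lapply(combos, function(members) {
      v <- rowSums(m[, members, drop = FALSE])
      if (pool == "mean") v <- v / k
      score_sample(setNames(v, rownames(m)), collection$genes, method,
                   expr_threshold = expr_threshold, alpha = alpha)
    })
    if (length(combos) < 2L) return(tibble())
    idx <- combn(length(combos), 2L)
    purrr::map_dfr(seq_len(ncol(idx)), function(p) {
      i <- idx[1L, p]; j <- idx[2L, p]
      if (disjoint_only && length(intersect(combos[[i]], combos[[j]])) > 0L) {
        return(tibble())
      }
      tibble(k = k, combo_a = combo_label(combos[[i]]),
             combo_b = combo_label(combos[[j]]),
             rho = spearman_cor(scores[[i]], scores[[j]]))
    })
  })
  summary <- if (nrow(pairs) == 0L) {
    tibble(k = integer(), median = numeric(), iqr = numeric(), n = integer())
  } else {
    pairs %>% group_by(.data$k) %>%
      summarise(median_iqr(.data$rho), .groups = "drop")
  }
  structure(
    list(pairs = pairs, summary = summary, method = method, pool = pool,
         expr_threshold = expr_threshold, disjoint_only = disjoint_only,
         n_replicates = length(reps), n_pathways = nrow(collection),
         platform = expr_platform(x)),
    class = "repro_result")
}
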