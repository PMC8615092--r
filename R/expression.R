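#' Aggregate transcript TPM to gene level
#'
#' Gene expression is the sum of the TPM of the gene's transcripts: TPM is
#' a relative unit, so summation conserves the total and a gene-level table
#' built from a complete quant table still sums to 1e6 over its mapped
#' part. Genes present in the map but absent from the quant table get TPM
#' 0.
#'
#' @param quants A transcript quantification tibble from
#'   [read_salmon_quant()] (columns `transcript_id`, `tpm` used).
#' @param tx2gene A transcript-to-gene map from [build_tx2gene_from_gtf()]
#'   (columns `transcript_id`, `gene_id`).
#' @param unmapped What to do with quantified transcripts missing from the
#'   map: `"drop"` (default) ignores them, `"error"` fails listing the
#'   offending IDs.
#'
#' @return A tibble with columns `gene_id` and `tpm`, genes ordered by
#'   first appearance in the map.
#' @export
aggregate_to_genes <- function(quants, tx2gene, unmapped = c("drop", "error")) {
  unmapped <- match.arg(unmapped)
  if (nrow(quants) == 0L) abort("Empty quant table")
  if (nrow(tx2gene) == 0L) abort("Empty transcript-to-gene map")
  hit <- match(quants$transcript_id, tx2gene$transcript_id)
  if (unmapped == "error" && anyNA(hit)) {
    off <- quants$transcript_id[is.na(hit)]
    abort(paste0("Unmapped transcript(s): ",
                 paste(head(off, 5L), collapse = ", "),
                 if (length(off) > 5L) sprintf(" (and %d more)", length(off) - 5L)))
  }
  genes <- unique(tx2gene$gene_id)
  tpm <- setNames(numeric(length(genes)), genes)
  ok <- !is.na(hit)
  sums <- tapply(quants$tpm[ok], tx2gene$gene_id[hit[ok]], sum)
  tpm[names(sums)] <- as.numeric(sums)
  tibble(gene_id = genes, tpm = unname(tpm))
}

#' Assemble an expression matrix from per-replicate quant tables
#'
#' @param quant_list Named list of quantification tibbles, one per
#'   replicate; names become replicate IDs.
#' @param tx2gene Transcript-to-gene map.
#' @param platform Optional platform label.
#' @inheritParams aggregate_to_genes
#' @return An expression tibble (see [expression_matrix()]).
#' @export
build_expression_matrix <- function(quant_list, tx2gene, platform = NULL,
                                    unmapped = c("drop", "error")) {
  unmapped <- match.arg(unmapped)
  if (length(quant_list) == 0L) abort("Need at least one quant table")
  if (is.null(names(quant_list)) || any(!nzchar(names(quant_list)))) {
    abort("`quant_list` must be a named list (names are replicate IDs)")
  }
  per_rep <- lapply(quant_list, aggregate_to_genes, tx2gene = tx2gene,
                    unmapped = unmapped)
  out <- tibble(gene_id = per_rep[[1L]]$gene_id)
  for (rep_id in names(per_rep)) out[[rep_id]] <- per_rep[[rep_id]]$tpm
  expression_matrix(out, platform = platform)
}

#' Detected features of a TPM vector
#'
#' A feature counts as detected when its TPM is strictly above the
#' threshold; the default 0 matches the convention that a Salmon target
#' with no assigned reads reports TPM 0.
#'
#' @param tpm Named non-negative numeric vector.
#' @param threshold Detection threshold (strict `>`); default 0.
#' @return Character vector of detected feature IDs.
#' @export
detect_features <- function(tpm, threshold = 0) {
  stopifnot(is.numeric(tpm), threshold >= 0)
  if (is.null(names(tpm))) abort("`tpm` must be a named vector")
  names(tpm)[tpm > threshold]
}

#' Remove low-expression features
#'
#' Features with TPM strictly below the threshold are removed (so a value
#' exactly at the threshold survives). Applied per scored sample ahead of
#' ranking; the default 0.1 TPM is the conventional low-expression cutoff.
#'
#' @inheritParams detect_features
#' @param threshold Removal threshold (strict `<`); default 0.1.
#' @return The filtered vector.
#' @export
filter_low_expression <- function(tpm, threshold = 0.1) {
  stopifnot(is.numeric(tpm), threshold >= 0)
  out <- tpm[tpm >= threshold]
  if (length(out) == 0L) abort("No genes survive low-expression filtering")
  out
}

#' Ascending midranks of a TPM vector
#'
#' Ranks are ascending (highest TPM gets rank N); ties receive the mean of
#' the rank positions they span, so the rank sum is always N(N+1)/2.
#'
#' @inheritParams detect_features
#' @return Numeric vector of midranks, names preserved.
#' @export
rank_genes <- function(tpm) {
  if (length(tpm) == 0L) abort("Cannot rank an empty vector")
  rank(tpm, ties.method = "average")
}

#' Per-gene coefficient of variation across replicates
#'
#' CV% = 100 * sd / mean per gene over the replicate columns, using the
#' sample (n-1) standard deviation. By default the computation is
#' restricted to genes detected (TPM > `detection_threshold`) in every
#' replicate, which also guarantees a positive mean.
#'
#' @param x An expression tibble with at least two replicate columns.
#' @param restrict_to_all_detected Keep only genes detected in all
#'   replicates (default `TRUE`).
#' @param detection_threshold Detection threshold passed to the
#'   restriction; default 0.
#' @return An object of class `cv_report`: use [tidy()] for the per-gene
#'   CVs and [glance()] for the one-row summary (`median_cv`,
#'   `n_genes_used`, `platform`).
#' @export
cv_report <- function(x, restrict_to_all_detected = TRUE,
                      detection_threshold = 0) {
  m <- expr_values(expression_matrix(x))
  if (ncol(m) < 2L) abort("CV needs at least 2 replicates")
  if (restrict_to_all_detected) {
    m <- m[rowSums(m > detection_threshold) == ncol(m), , drop = FALSE]
  }
  if (nrow(m) == 0L) abort("No genes detected in all replicates")
  mu <- rowMeans(m)
  if (any(mu == 0)) abort("Gene with zero mean; restrict to detected genes")
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
  structure(
    list(per_gene = tibble(gene_id = rownames(m), cv = unname(100 * s / mu)),
         median_cv = median(100 * s / mu),
         n_genes_used = nrow(m),
         n_replicates = ncol(m),
         platform = expr_platform(x)),
    class = "cv_report")
}

#' Pairwise Spearman correlation between replicates
#'
#' Off-diagonal entries are the Spearman correlation of two replicates'
#' TPM over the shared gene universe (by default genes detected in all
#' replicates). A constant replicate yields `NA` off-diagonals; the
#' diagonal is 1 by definition.
#'
#' @inheritParams cv_report
#' @param method Correlation method; only `"spearman"` is supported.
#' @return A symmetric numeric matrix with replicate IDs as dimnames.
#' @export
replicate_correlation <- function(x, method = "spearman",
                                  restrict_to_all_detected = TRUE,
                                  detection_threshold = 0) {
  method <- match.arg(method, "spearman")
  m <- expr_values(expression_matrix(x))
  if (ncol(m) < 2L) abort("Need at least 2 replicates")
  if (restrict_to_all_detected) {
    m <- m[rowSums(m > detection_threshold) == ncol(m), , drop = FALSE]
  }
  if (nrow(m) == 0L) abort("No genes detected in all replicates")
  out <- matrix(NA_real_, ncol(m), ncol(m),
                dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(ncol(m))) {
    for (j in seq_len(ncol(m))) {
      if (j > i) next
      out[i, j] <- out[j, i] <-
        if (i == j) 1 else spearman_cor(m[, i], m[, j])
    }
  }
  out
}

#' Cross-platform agreement of mean gene ranks
#'
#' Each platform's replicates are ranked over that platform's full gene
#' universe (undetected genes carry TPM 0 and tie at the bottom via
#' midranks), ranks are averaged across replicates, and the two mean-rank
#' vectors are compared by Pearson correlation over the genes detected in
#' at least one replicate of *both* platforms. Genes detected on only one
#' platform are reported separately (the "spurs" of a rank-rank scatter);
#' `include_exclusive = TRUE` keeps them in the correlation instead.
#'
#' @param a,b Expression tibbles for the two platforms. Gene universes may
#'   differ; only genes present in both tables can enter the correlation.
#' @param detection_threshold Detection threshold (strict `>`); default 0.
#' @param include_exclusive Include platform-exclusive genes in the Pearson
#'   correlation (default `FALSE`).
#' @return An object of class `rank_agreement` with the correlation
#'   (`pearson`), the per-gene mean ranks (`mean_ranks`), and the
#'   platform-exclusive gene lists (`exclusive_a`, `exclusive_b`).
#'   [tidy()] returns the per-gene table, [glance()] the one-row summary.
#' @export
cross_platform_rank_agreement <- function(a, b, detection_threshold = 0,
                                          include_exclusive = FALSE) {
  ma <- expr_values(expression_matrix(a))
  mb <- expr_values(expression_matrix(b))
  if (nrow(ma) == 0L || nrow(mb) == 0L) abort("Empty expression matrix")
  mean_rank <- function(m) rowMeans(apply(m, 2L, rank_genes))
  ra <- mean_rank(ma)
  rb <- mean_rank(mb)
  det_a <- rownames(ma)[rowSums(ma > detection_threshold) > 0]
  det_b <- rownames(mb)[rowSums(mb > detection_threshold) > 0]
  shared_universe <- intersect(rownames(ma), rownames(mb))
  both <- intersect(intersect(det_a, det_b), shared_universe)
  only_a <- intersect(setdiff(det_a, det_b), shared_universe)
  only_b <- intersect(setdiff(det_b, det_a), shared_universe)
  use <- if (include_exclusive) union(both, union(only_a, only_b)) else both
  if (length(use) < 3L) abort("Fewer than 3 genes shared between platforms")
  structure(
    list(pearson = cor(ra[use], rb[use]),
         mean_ranks = tibble(
           gene_id = shared_universe,
           mean_rank_a = unname(ra[shared_universe]),
           mean_rank_b = unname(rb[shared_universe]),
           detected_a = shared_universe %in% det_a,
           detected_b = shared_universe %in% det_b),
         exclusive_a = only_a, exclusive_b = only_b,
         include_exclusive = include_exclusive,
         n_genes_used = length(use),
         platform_a = expr_platform(a), platform_b = expr_platform(b)),
    class = "rank_agreement")
}
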