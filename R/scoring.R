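#' Single-sample ssGSEA enrichment score
#'
#' The ssGSEA statistic for one sample and one gene set is the summed
#' difference between two empirical cumulative distribution functions
#' walked over the genes in decreasing expression-rank order: a weighted
#' ECDF of the in-set genes (weights are the ascending midranks raised to
#' `alpha`) and an unweighted ECDF of the out-of-set genes,
#'
#' \deqn{ES = \sum_{i=1}^{N} \left[ P_{in}(i) - P_{out}(i) \right]}
#'
#' with \eqn{P_{in}(i) = \sum_{j \le i,\, g_j \in S} r_{g_j}^\alpha /
#' \sum_{g \in S} r_g^\alpha} and \eqn{P_{out}(i) = |\{j \le i : g_j \notin
#' S\}| / (N - |S|)}. The score depends on the expression values only
#' through their midranks, so any strictly monotone transform of the input
#' leaves it unchanged. Genes of the set that are absent from the
#' expression vector are ignored; a set covering none or all of the
#' universe has no defined score and yields `NA`.
#'
#' @param tpm Named numeric vector of expression values (one sample).
#' @param genes Character vector: the gene set.
#' @param alpha Rank-weighting exponent, >= 0; default 0.25.
#' @return A single numeric enrichment score, or `NA` when undefined.
#' @examples
#' ssgsea_score(c(a = 8, b = 4, c = 2, d = 1), c("a", "b"))
#' @export
ssgsea_score <- function(tpm, genes, alpha = 0.25) {
  check_sample(tpm)
  stopifnot(alpha >= 0)
  ord <- prepare_sample(tpm, alpha)
  ssgsea_engine(ord, match_set(genes, ord$gene_ids))
}

#' Single-sample singscore
#'
#' The singscore of a gene set is its mean gene rank, linearly rescaled so
#' that the attainable range maps onto [0, 1]: with ascending midranks
#' \eqn{r}, set size \eqn{n} (genes of the set present in the universe) and
#' universe size \eqn{N},
#'
#' \deqn{score = \frac{\bar r_S - (n+1)/2}{N - n}}
#'
#' The minimum \eqn{(n+1)/2} is the mean rank of the bottom-n set and the
#' maximum is attained by the top-n set, so 0 and 1 are reached exactly.
#' It is directly interpretable as a normalized mean percentile rank, and —
#' like the ssGSEA score — depends on expression only through midranks.
#' Unidirectional sets only (no up/down split).
#'
#' @inheritParams ssgsea_score
#' @param center Shift the score from [0, 1] to [-0.5, 0.5]
#'   (default `FALSE`).
#' @return A single numeric score, or `NA` when the set covers none or all
#'   of the universe.
#' @examples
#' singscore_score(c(a = 10, b = 5, c = 3, d = 2, e = 1), c("a", "c"))
#' @export
singscore_score <- function(tpm, genes, center = FALSE) {
  check_sample(tpm)
  ord <- prepare_sample(tpm, alpha = 1)
  singscore_engine(ord, match_set(genes, ord$gene_ids), center)
}

#' Score a pathway collection across samples
#'
#' Applies one of the two single-sample scoring methods to every pathway
#' and every sample column of an expression matrix. Each sample is
#' low-expression filtered on its own (TPM below `expr_threshold` removed)
#' before ranking, so each column defines its own gene universe. Pathways
#' with no scorable genes in a sample get `NA` there.
#'
#' For ssGSEA, `normalize = TRUE` (the convention of the standard
#' implementation) divides the full score table by its global max - min
#' range; this is a single positive rescaling, so rank-based comparisons
#' between samples are unaffected by the flag.
#'
#' @param x An expression tibble (see [expression_matrix()]).
#' @param collection A gene-set tibble (see [read_gmt()]), usually
#'   pre-filtered with [filter_collection()].
#' @param method `"singscore"` or `"ssgsea"`.
#' @param expr_threshold Per-sample low-expression cutoff (strict `<`
#'   removal); default 0.1 TPM.
#' @param alpha ssGSEA rank-weight exponent; default 0.25.
#' @param normalize ssGSEA global range normalization; default `TRUE`.
#' @param center singscore centering to [-0.5, 0.5]; default `FALSE`.
#' @return A tibble with a `pathway` column and one numeric column per
#'   sample, with attribute `method`.
#' @export
score_pathways <- function(x, collection, method = c("singscore", "ssgsea"),
                           expr_threshold = 0.1, alpha = 0.25,
                           normalize = TRUE, center = FALSE) {
  method <- match.arg(method)
  check_collection(collection)
  m <- expr_values(expression_matrix(x))
  scores <- vapply(seq_len(ncol(m)), function(j) {
    score_sample(setNames(m[, j], rownames(m)), collection$genes, method,
                 expr_threshold = expr_threshold, alpha = alpha,
                 center = center)
  }, numeric(nrow(collection)))
  scores <- matrix(scores, nrow = nrow(collection),
                   dimnames = list(NULL, colnames(m)))
  if (all(is.na(scores))) abort("All pathway scores are missing")
  if (method == "ssgsea" && normalize) {
    rng <- range(scores, na.rm = TRUE)
    if (diff(rng) > 0) scores <- scores / diff(rng)
  }
  out <- tibble(pathway = collection$name)
  for (j in colnames(scores)) out[[j]] <- scores[, j]
  attr(out, "method") <- method
  out
}

# ---- internal scoring engine -----------------------------------------------

check_sample <- function(tpm) {
  if (length(tpm) < 2L) abort("Need at least 2 genes to score")
  if (is.null(names(tpm))) abort("Expression vector must be named by gene")
}

# Rank a sample once; reused across all pathways of a collection.
# Genes are laid out in decreasing midrank order (ties keep input order),
# with cumulative quantities precomputable per pathway.
prepare_sample <- function(tpm, alpha) {
  r <- rank_genes(tpm)
  ord <- order(r, decreasing = TRUE)
  list(gene_ids = names(tpm)[ord], r = r[ord], ra = r[ord]^alpha,
       n = length(tpm))
}

match_set <- function(genes, gene_ids) {
  idx <- match(unique(genes), gene_ids)
  idx[!is.na(idx)]
}

ssgsea_engine <- function(ord, idx) {
  n_in <- length(idx)
  if (n_in == 0L || n_in == ord$n) return(NA_real_)
  ind <- logical(ord$n)
  ind[idx] <- TRUE
  p_in <- cumsum(ord$ra * ind) / sum(ord$ra[ind])
  p_out <- cumsum(!ind) / (ord$n - n_in)
  sum(p_in - p_out)
}

singscore_engine <- function(ord, idx, center) {
  n_in <- length(idx)
  if (n_in == 0L || n_in == ord$n) return(NA_real_)
  s <- (mean(ord$r[idx]) - (n_in + 1) / 2) / (ord$n - n_in)
  if (center) s - 0.5 else s
}

# Score every pathway of a collection for one sample vector.
score_sample <- function(tpm, gene_sets, method, expr_threshold = 0.1,
                         alpha = 0.25, center = FALSE) {
  x <- filter_low_expression(tpm, expr_threshold)
  if (length(x) < 2L) abort("Fewer than 2 genes after expression filtering")
  ord <- prepare_sample(x, alpha)
  vapply(gene_sets, function(g) {
    idx <- match_set(g, ord$gene_ids)
    if (method == "ssgsea") ssgsea_engine(ord, idx)
    else singscore_engine(ord, idx, center)
  }, numeric(1))
}
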