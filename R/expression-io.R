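#' Expression matrices
#'
#' An expression matrix is an ordinary tibble whose first column, `gene_id`,
#' holds unique gene identifiers and whose remaining columns hold
#' non-negative TPM values, one column per sequencing replicate. A platform
#' label ("ONT", "ILMN", "synthetic", ...) may travel along as the
#' `platform` attribute; it is purely descriptive.
#'
#' @param x A data frame with a `gene_id` column and numeric replicate
#'   columns.
#' @param platform Optional platform label.
#' @return A validated expression tibble.
#' @export
expression_matrix <- function(x, platform = NULL) {
  x <- as_tibble(x)
  if (names(x)[1L] != "gene_id") {
    abort("First column of an expression matrix must be `gene_id`")
  }
  if (ncol(x) < 2L) abort("Expression matrix needs at least one replicate column")
  if (anyDuplicated(x$gene_id)) {
    abort(paste0("Duplicate gene_id: ", x$gene_id[duplicated(x$gene_id)][1L]))
  }
  vals <- x[-1L]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    abort("Replicate columns must be numeric")
  }
  if (any(vapply(vals, function(v) any(v < 0, na.rm = TRUE), logical(1)))) {
    abort("TPM values must be non-negative")
  }
  if (!is.null(platform)) attr(x, "platform") <- platform
  x
}

#' @rdname expression_matrix
#' @export
replicate_ids <- function(x) setdiff(names(x), "gene_id")

# gene x replicate numeric matrix with gene_id rownames
expr_values <- function(x) {
  m <- as.matrix(x[-1L])
  rownames(m) <- x$gene_id
  m
}

expr_platform <- function(x) {
  p <- attr(x, "platform")
  if (is.null(p)) NA_character_ else p
}

#' Read / write a gene-by-replicate TPM table
#'
#' Plain TSV with a header row: `gene_id` first, then one column per
#' replicate. Values are written with 6 significant digits, so
#' `write_expression_matrix(read_expression_matrix(f), f2)` reproduces a
#' file previously written by this writer byte for byte.
#'
#' @param path File path.
#' @param platform Optional platform label attached to the result.
#' @return `read_expression_matrix()` returns an expression tibble;
#'   `write_expression_matrix()` returns `path` invisibly.
#' @export
read_expression_matrix <- function(path, platform = NULL) {
  if (!file.exists(path)) abort(paste0("matrix file not found: ", path))
  dat <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE))
  probs <- readr::problems(dat)
  if (nrow(probs) > 0L) {
    abort(sprintf("Malformed matrix TSV (%d parsing problem(s); first at line %d)",
                  nrow(probs), probs$row[1L]))
  }
  if (!"gene_id" %in% names(dat)) {
    abort("matrix TSV must have a `gene_id` first column")
  }
  expression_matrix(dat, platform = platform)
}

#' @rdname read_expression_matrix
#' @param x An expression tibble.
#' @export
write_expression_matrix <- function(x, path) {
  x <- expression_matrix(x)
  cols <- c(list(x$gene_id),
            lapply(x[-1L], function(v) formatC(v, digits = 6, format = "g")))
  lines <- c(paste(names(x), collapse = "\t"),
             do.call(paste, c(cols, sep = "\t")))
  readr::write_lines(lines, path)
  invisible(path)
}
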