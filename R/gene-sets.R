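#' Read a gene-set collection from a GMT file
#'
#' GMT is the de-facto exchange format for gene-set collections
#' (MSigDB, WikiPathways): one set per line, tab-separated, with the set
#' name in the first field, a free-text description in the second, and the
#' member genes in the remaining fields.
#'
#' @param path Path to a GMT file.
#'
#' @return A tibble with one row per gene set and columns `name` (character),
#'   `description` (character, possibly empty) and `genes` (list column of
#'   character vectors, duplicates within a set collapsed). Row order follows
#'   the file.
#'
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines("WP1\tdemo pathway\tTP53\tMDM2\tCDKN1A", gmt)
#' read_gmt(gmt)
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("GMT file not found: ", path))
  }
  lines <- readr::read_lines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(tibble(name = character(), description = character(),
                  genes = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Malformed GMT line %d: expected at least 2 tab-separated fields",
      which(keep)[bad[1L]]))
  }
  name <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(name)) {
    dup <- name[duplicated(name)][1L]
    abort(paste0("Duplicate gene-set name in GMT: ", dup))
  }
  description <- vapply(fields, `[[`, character(1), 2L)
  genes <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  tibble(name = name, description = description, genes = genes)
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection A tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  check_collection(collection)
  lines <- purrr::pmap_chr(
    list(collection$name, collection$description, collection$genes),
    function(n, d, g) paste(c(n, d, g), collapse = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Drop gene sets smaller than a minimum size
#'
#' Pathway collections are filtered once, globally, before any scoring:
#' sets with fewer than `min_genes` members are removed (strictly fewer, so
#' a set of exactly `min_genes` genes is kept). Membership is counted on the
#' raw set, not on its intersection with any expression universe, because
#' the size filter is an annotation-level decision while expression
#' filtering happens per sample.
#'
#' @param collection A gene-set tibble (see [read_gmt()]).
#' @param min_genes Minimum set size kept; default 5.
#' @return The filtered collection, input order preserved.
#' @export
filter_collection <- function(collection, min_genes = 5) {
  check_collection(collection)
  if (!is.numeric(min_genes) || length(min_genes) != 1L || min_genes < 1) {
    abort("`min_genes` must be a single number >= 1")
  }
  out <- collection[lengths(collection$genes) >= min_genes, , drop = FALSE]
  if (nrow(out) == 0L) {
    abort(sprintf("No gene sets with at least %d genes remain", min_genes))
  }
  out
}

check_collection <- function(collection) {
  if (!is.data.frame(collection) ||
      !all(c("name", "genes") %in% names(collection))) {
    abort("A gene-set collection needs columns `name` and `genes`")
  }
  if (anyDuplicated(collection$name)) {
    abort("Gene-set names must be unique")
  }
  if (!is.list(collection$genes)) {
    abort("`genes` must be a list column of character vectors")
  }
  invisible(collection)
}
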