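#' Build a transcript-to-gene map from an Ensembl GTF
#'
#' Restricts an Ensembl-style annotation to protein-coding transcripts the
#' way a gene-level TPM analysis expects: rows of feature type
#' `transcript`, with `gene_biotype` and `transcript_biotype` both
#' `protein_coding`, carrying the `basic` tag (when `require_basic_tag` is
#' on), and located on a standard chromosome (defaults 1-22, X, Y, MT —
#' scaffolds and patches are dropped).
#'
#' Attribute extraction is done with targeted regexes on the raw ninth
#' column rather than a generic GTF reader: the `tag` key legitimately
#' repeats within one attribute field (`tag "basic"; tag "CCDS";`) and
#' generic readers collapse repeated keys to a single value, which would
#' silently drop transcripts from the `basic` filter. Both `key "value";`
#' and `key "value" ;` spacings are accepted.
#'
#' @param path Path to a GTF file (plain or gzip; Ensembl dialect).
#' @param require_basic_tag Keep only transcripts tagged `basic`
#'   (default `TRUE`).
#' @param standard_chromosomes Chromosome names retained; default
#'   `c(1:22, "X", "Y", "MT")`.
#'
#' @return A tibble with columns `transcript_id` and `gene_id`, one row per
#'   retained transcript, in file order. Attributes `n_transcripts` and
#'   `n_genes` record the mapped transcript and distinct gene counts.
#' @export
build_tx2gene_from_gtf <- function(path,
                                   require_basic_tag = TRUE,
                                   standard_chromosomes =
                                     c(as.character(1:22), "X", "Y", "MT")) {
  if (!file.exists(path)) {
    abort(paste0("GTF file not found: ", path))
  }
  lines <- readr::read_lines(path, progress = FALSE)
  body <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (length(body) == 0L) {
    return(new_tx2gene(tibble(transcript_id = character(),
                              gene_id = character())))
  }
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad) > 0L) {
    abort(sprintf("GTF line %d does not have 9 tab-separated columns",
                  body[bad[1L]]))
  }
  seqname <- vapply(fields, `[[`, character(1), 1L)
  feature <- vapply(fields, `[[`, character(1), 3L)
  attrs <- vapply(fields, `[[`, character(1), 9L)

  keep <- feature == "transcript" & seqname %in% standard_chromosomes
  keep <- keep &
    gtf_attr(attrs, "gene_biotype") %in% "protein_coding" &
    gtf_attr(attrs, "transcript_biotype") %in% "protein_coding"
  if (require_basic_tag) {
    keep <- keep & stringr::str_detect(attrs, "tag\\s+\"basic\"")
  }
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) {
    return(new_tx2gene(tibble(transcript_id = character(),
                              gene_id = character())))
  }

  tx <- gtf_attr(attrs[keep], "transcript_id")
  gene <- gtf_attr(attrs[keep], "gene_id")
  missing <- which(is.na(tx) | is.na(gene))
  if (length(missing) > 0L) {
    abort(sprintf(
      "GTF line %d: transcript row without transcript_id/gene_id attribute",
      body[keep][missing[1L]]))
  }
  map <- distinct(tibble(transcript_id = tx, gene_id = gene))
  if (anyDuplicated(map$transcript_id)) {
    off <- unique(map$transcript_id[duplicated(map$transcript_id)])
    abort(paste0("Transcript(s) mapped to more than one gene: ",
                 paste(head(off, 5L), collapse = ", ")))
  }
  new_tx2gene(map)
}

new_tx2gene <- function(map) {
  attr(map, "n_transcripts") <- nrow(map)
  attr(map, "n_genes") <- n_distinct(map$gene_id)
  map
}

# First value of `key "value"` in a GTF attribute string, NA when absent.
gtf_attr <- function(attrs, key) {
  stringr::str_match(attrs, paste0(key, "\\s+\"([^\"]*)\""))[, 2L]
}
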