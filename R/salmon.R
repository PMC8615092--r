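#' Read a Salmon quant.sf transcript quantification table
#'
#' Salmon writes one `quant.sf` per sample: a TSV with the exact header
#' `Name  Length  EffectiveLength  TPM  NumReads`. Ensembl quantification
#' targets usually carry a version suffix (`ENST00000367770.8`); by default
#' the suffix is stripped so the IDs join a GTF-derived transcript-to-gene
#' map.
#'
#' @param path Path to a `quant.sf` file.
#' @param strip_versions Remove a trailing `.N` version from transcript IDs
#'   (default `TRUE`).
#'
#' @return A tibble with columns `transcript_id`, `length`,
#'   `effective_length`, `tpm`, `num_reads`, one row per transcript.
#' @export
read_salmon_quant <- function(path, strip_versions = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("quant file not found: ", path))
  }
  expected <- c("Name", "Length", "EffectiveLength", "TPM", "NumReads")
  hdr <- strsplit(readr::read_lines(path, n_max = 1L), "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, expected)) {
    abort(paste0("Not a Salmon quant.sf header; expected exactly: ",
                 paste(expected, collapse = "/")))
  }
  dat <- readr::read_tsv(path, col_types = readr::cols(
    Name = readr::col_character(), Length = readr::col_double(),
    EffectiveLength = readr::col_double(), TPM = readr::col_double(),
    NumReads = readr::col_double()), progress = FALSE)
  id <- dat$Name
  if (strip_versions) id <- sub("\\.\\d+$", "", id)
  if (anyDuplicated(id)) {
    abort(paste0("Duplicate transcript ID in quant table: ",
                 id[duplicated(id)][1L]))
  }
  if (any(dat$TPM < 0)) abort("Negative TPM value in quant table")
  if (any(dat$Length < 1)) abort("Transcript length below 1 in quant table")
  tibble(transcript_id = id, length = dat$Length,
         effective_length = dat$EffectiveLength,
         tpm = dat$TPM, num_reads = dat$NumReads)
}
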