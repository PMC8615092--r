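# Programmatic fixtures shared across tests. Everything is built in code;
# no files ship with the package.

write_quant_file <- function(rows, path = tempfile(fileext = ".sf")) {
  header <- "Name\tLength\tEffectiveLength\tTPM\tNumReads"
  writeLines(c(header, rows), path)
  path
}

quant_row <- function(name, tpm, length = 1000, eff = 800.5, reads = 10) {
  sprintf("%s\t%d\t%s\t%s\t%s", name, length, eff, tpm, reads)
}

# Minimal Ensembl-dialect GTF transcript line.
gtf_line <- function(chrom = "1", feature = "transcript", gene = "G1",
                     tx = "T1", gene_biotype = "protein_coding",
                     tx_biotype = "protein_coding", tags = "basic") {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s"; transcript_biotype "%s";',
                   gene, tx, gene_biotype, tx_biotype)
  for (t in tags) attrs <- paste0(attrs, sprintf(' tag "%s";', t))
  sprintf("%s\tensembl\t%s\t100\t200\t.\t+\t.\t%s", chrom, feature, attrs)
}

write_gtf_file <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(c("#!genome-build test", lines), path)
  path
}

toy_matrix <- function(values, gene_ids = NULL, platform = NULL) {
  m <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m)) || anyDuplicated(colnames(m))) {
    colnames(m) <- paste0("r", seq_len(ncol(m)))
  }
  out <- tibble::as_tibble(m)
  out <- dplyr::bind_cols(tibble::tibble(gene_id = gene_ids), out)
  expression_matrix(out, platform = platform)
}

toy_collection <- function(sets, descriptions = NULL) {
  tibble::tibble(
    name = names(sets),
    description = descriptions %||% rep("", length(sets)),
    genes = unname(sets))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small synthetic experiment reused by several slow-ish tests.
small_sim <- function(seed = 42, n_replicates = 3, depth = 5e4,
                      n_genes = 400, n_pathways = 15) {
  cfg <- synthetic_config(
    n_genes = n_genes, n_pathways = n_pathways,
    pathway_size_range = c(5, 25), seed = seed,
    profiles = platform_profile("SYN", depth, 0.3, n_replicates))
  simulate_experiment(cfg)
}
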