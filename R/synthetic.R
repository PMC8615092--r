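#' Platform sequencing profiles for the synthetic generator
#'
#' A profile bundles the depth and noise behaviour of one sequencing
#' platform: the expected total mapped read count, the standard deviation
#' of the per-gene log-normal replicate effect (multiplicative technical
#' noise), and how many replicates to simulate. The two built-in profiles
#' emulate a MinION direct RNA-seq run (about 1.5 million mapped reads,
#' noise calibrated so the median per-gene CV across replicates lands near
#' one third) and a NovaSeq short-read run (tens of millions of reads,
#' somewhat tighter noise).
#'
#' @param name Platform label.
#' @param depth Expected total mapped reads (>= 1000).
#' @param noise_sd Standard deviation of the per-gene log-normal replicate
#'   effect (>= 0).
#' @param n_replicates Number of replicates to simulate.
#' @return One-row tibble describing the profile.
#' @export
platform_profile <- function(name, depth, noise_sd, n_replicates) {
  stopifnot(is.character(name), length(name) == 1L,
            depth >= 1e3, noise_sd >= 0, n_replicates >= 1)
  tibble(name = name, depth = depth, noise_sd = noise_sd,
         n_replicates = as.integer(n_replicates))
}

#' @rdname platform_profile
#' @export
ont_profile <- function(depth = 1.5e6, noise_sd = 0.33, n_replicates = 5) {
  platform_profile("ONT", depth, noise_sd, n_replicates)
}

#' @rdname platform_profile
#' @export
illumina_profile <- function(depth = 5e7, noise_sd = 0.26, n_replicates = 3) {
  platform_profile("ILMN", depth, noise_sd, n_replicates)
}

#' Configuration of a synthetic replicate experiment
#'
#' Collects every parameter of the simulator: the number of genes, the
#' log-normal abundance distribution (meanlog/sdlog on the natural-log
#' scale; the scale itself is irrelevant because abundances are
#' normalized before sampling), the platform profiles, the random pathway
#' collection (count and size range), optional pathway activations
#' (name -> fold factor applied to member-gene abundances), and the seed
#' that makes the whole experiment deterministic.
#'
#' @param n_genes Number of genes in the catalog.
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance
#'   parameters; defaults 0 and 2.2 give the heavy-tailed dynamic range
#'   typical of bulk transcriptomes.
#' @param profiles Tibble of platform profiles (rows from
#'   [platform_profile()]); default ONT-like plus Illumina-like.
#' @param n_pathways Number of random pathways generated.
#' @param pathway_size_range Two integers: min and max pathway size.
#' @param tx_per_gene_range Two integers: min and max transcripts per gene
#'   (transcript shares let gene-level aggregation be exercised
#'   end-to-end).
#' @param activation Optional named numeric vector of fold factors,
#'   names are pathway names (`pw001`, ...).
#' @param seed Integer seed; identical configs produce identical
#'   experiments.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 10000,
                             abundance_meanlog = 0, abundance_sdlog = 2.2,
                             profiles = bind_rows(ont_profile(),
                                                  illumina_profile()),
                             n_pathways = 200,
                             pathway_size_range = c(10, 100),
                             tx_per_gene_range = c(1, 3),
                             activation = NULL, seed = 1) {
  stopifnot(n_genes >= 10, abundance_sdlog >= 0, n_pathways >= 1,
            length(pathway_size_range) == 2L,
            pathway_size_range[1] >= 1,
            pathway_size_range[1] <= pathway_size_range[2],
            length(tx_per_gene_range) == 2L, tx_per_gene_range[1] >= 1)
  if (pathway_size_range[2] > n_genes) {
    abort("Pathway size range exceeds the number of genes")
  }
  if (!is.null(activation)) {
    stopifnot(is.numeric(activation), all(activation > 0),
              !is.null(names(activation)))
  }
  structure(list(n_genes = as.integer(n_genes),
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 profiles = profiles,
                 n_pathways = as.integer(n_pathways),
                 pathway_size_range = as.integer(pathway_size_range),
                 tx_per_gene_range = as.integer(tx_per_gene_range),
                 activation = activation,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a gene catalog with ground-truth abundances and pathways
#'
#' Draws i.i.d. log-normal true abundances per gene, splits each gene into
#' 1-3 transcripts with random shares, and samples pathways as uniform
#' random gene subsets within the configured size range. Deterministic
#' given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A `gene_catalog`: list with `genes` (tibble `gene_id`,
#'   `abundance`), `transcripts` (tibble `transcript_id`, `gene_id`,
#'   `share`; shares sum to 1 per gene), and `pathways` (gene-set tibble
#'   usable with [score_pathways()]).
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  abundance <- rlnorm(config$n_genes, config$abundance_meanlog,
                      config$abundance_sdlog)
  n_tx <- sample(seq(config$tx_per_gene_range[1], config$tx_per_gene_range[2]),
                 config$n_genes, replace = TRUE)
  shares <- lapply(n_tx, function(k) {
    w <- stats::rexp(k)
    w / sum(w)
  })
  transcripts <- tibble(
    gene_id = rep(gene_ids, n_tx),
    share = unlist(shares)) %>%
    group_by(.data$gene_id) %>%
    mutate(transcript_id = paste0(.data$gene_id, ".t", row_number())) %>%
    ungroup() %>%
    select("transcript_id", "gene_id", "share")
  sizes <- sample(seq(config$pathway_size_range[1],
                      config$pathway_size_range[2]),
                  config$n_pathways, replace = TRUE)
  pathways <- tibble(
    name = sprintf("pw%03d", seq_len(config$n_pathways)),
    description = "synthetic pathway",
    genes = lapply(sizes, function(k) sample(gene_ids, k)))
  catalog <- structure(
    list(genes = tibble(gene_id = gene_ids, abundance = abundance),
         transcripts = transcripts, pathways = pathways),
    class = "gene_catalog")
  if (!is.null(config$activation)) {
    catalog <- inject_activation(catalog, names(config$activation),
                                 config$activation)
  }
  catalog
}

#' Multiply the abundance of a pathway's member genes
#'
#' Emulates pathway activation by scaling the true abundance of every
#' member gene by `fold`; all other genes are untouched. Injecting and
#' then dividing by the same fold restores the catalog exactly.
#'
#' @param catalog A `gene_catalog`.
#' @param pathway_names Character vector of pathway names in the catalog.
#' @param fold Positive fold factor(s), recycled along `pathway_names`.
#' @return The modified catalog.
#' @export
inject_activation <- function(catalog, pathway_names, fold) {
  stopifnot(inherits(catalog, "gene_catalog"), all(fold > 0))
  fold <- rep_len(fold, length(pathway_names))
  unknown <- setdiff(pathway_names, catalog$pathways$name)
  if (length(unknown) > 0L) {
    abort(paste0("Unknown pathway(s): ", paste(unknown, collapse = ", ")))
  }
  ab <- setNames(catalog$genes$abundance, catalog$genes$gene_id)
  for (i in seq_along(pathway_names)) {
    members <- catalog$pathways$genes[[
      match(pathway_names[i], catalog$pathways$name)]]
    ab[members] <- ab[members] * fold[i]
  }
  catalog$genes$abundance <- unname(ab)
  catalog
}

#' Simulate one sequencing replicate
#'
#' One replicate is a depth-limited sample of the catalog: each gene's
#' rate is its true abundance times a fresh log-normal replicate effect
#' `exp(N(0, noise_sd^2))`; read counts are Poisson with mean
#' `depth * rate / sum(rate)`; TPM is the count scaled to a million.
#' Genes with zero sampled reads get TPM 0, so dropout emerges from depth
#' rather than being imposed — low-depth profiles lose low-abundance
#' genes first, exactly the behaviour that limits single-replicate
#' nanopore runs.
#'
#' @param catalog A `gene_catalog`.
#' @param profile A one-row profile tibble ([platform_profile()]).
#' @param seed Integer seed for this replicate.
#' @return Tibble with columns `gene_id` and `tpm`; TPM sums to exactly
#'   1e6.
#' @export
simulate_replicate <- function(catalog, profile, seed) {
  stopifnot(inherits(catalog, "gene_catalog"), nrow(profile) == 1L)
  set.seed(seed)
  rate <- catalog$genes$abundance *
    exp(rnorm(nrow(catalog$genes), 0, profile$noise_sd))
  counts <- rpois(length(rate), profile$depth * rate / sum(rate))
  total <- sum(counts)
  if (total == 0L) abort("Depth too low: no reads sampled")
  tibble(gene_id = catalog$genes$gene_id, tpm = 1e6 * counts / total)
}

#' Simulate a full multi-platform replicate experiment
#'
#' Generates (or reuses) a catalog and simulates every configured
#' platform profile, with per-replicate sub-seeds derived from the config
#' seed, so the whole experiment is reproducible and replicates are
#' mutually independent. Supplying `catalog` reuses the same sub-seed
#' stream, which pairs the sampling noise between runs on modified
#' catalogs (e.g. before/after [inject_activation()]).
#'
#' @param config A [synthetic_config()].
#' @param catalog Optional pre-built `gene_catalog` (defaults to
#'   `generate_catalog(config)`).
#' @return List with `matrices` (named list of expression tibbles, one
#'   per profile, platform attribute set), `catalog`, and `config`.
#' @export
simulate_experiment <- function(config, catalog = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(catalog)) catalog <- generate_catalog(config)
  n_total <- sum(config$profiles$n_replicates)
  set.seed(config$seed + 1L)
  sub_seeds <- sample.int(.Machine$integer.max, n_total)
  matrices <- list()
  used <- 0L
  for (i in seq_len(nrow(config$profiles))) {
    prof <- config$profiles[i, ]
    cols <- lapply(seq_len(prof$n_replicates), function(j) {
      simulate_replicate(catalog, prof, sub_seeds[used + j])
    })
    used <- used + prof$n_replicates
    out <- tibble(gene_id = catalog$genes$gene_id)
    for (j in seq_along(cols)) {
      out[[paste0(prof$name, "-", j)]] <- cols[[j]]$tpm
    }
    matrices[[prof$name]] <- expression_matrix(out, platform = prof$name)
  }
  list(matrices = matrices, catalog = catalog, config = config)
}

#' Expand a simulated gene TPM vector to a transcript quantification table
#'
#' Distributes each gene's TPM over its transcripts according to the
#' catalog's ground-truth shares, yielding a table shaped like a Salmon
#' quantification so the transcript-to-gene aggregation step can be
#' exercised end-to-end on synthetic data.
#'
#' @param catalog A `gene_catalog`.
#' @param tpm Tibble with `gene_id` and `tpm` (e.g. from
#'   [simulate_replicate()]).
#' @return Tibble with columns `transcript_id`, `length`,
#'   `effective_length`, `tpm`, `num_reads` (lengths are nominal).
#' @export
transcript_quant <- function(catalog, tpm) {
  stopifnot(inherits(catalog, "gene_catalog"))
  tx <- left_join(catalog$transcripts, tpm, by = "gene_id")
  tibble(transcript_id = tx$transcript_id,
         length = 1000, effective_length = 800,
         tpm = tx$share * tx$tpm,
         num_reads = tx$share * tx$tpm)
}
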