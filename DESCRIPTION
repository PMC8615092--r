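Package: pathrepro
Title: Replicate Requirements for Single-Sample Pathway Activation Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how many sequencing replicates are needed for stable
    single-sample pathway activation scores, with an emphasis on low-depth
    long-read (nanopore direct RNA-seq) experiments. Implements two
    rank-based single-sample scoring methods (a weighted-ECDF enrichment sum
    in the ssGSEA style and a normalized mean-rank singscore), gene-level TPM
    aggregation from Salmon transcript quantifications with protein-coding
    GTF filtering, replicate reproducibility statistics (per-gene coefficient
    of variation, pairwise Spearman correlation, cross-platform mean-rank
    agreement), an exhaustive replicate-combination scheme for detection
    saturation curves and pathway-score reproducibility (median and IQR of
    pairwise Spearman correlations per combination size), and a calibrated
    synthetic replicate generator (log-normal abundances, depth-limited
    Poisson sampling with dropout, per-replicate multiplicative noise,
    injectable pathway activation) so the whole pipeline can be exercised
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
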