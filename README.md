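# pathrepro

How many sequencing replicates do you need before single-sample pathway
activation scores stop wobbling? The question bites hardest for nanopore
direct RNA-seq, where one MinION flow cell yields ~1–2 million mapped
reads — enough to rank the well-expressed transcriptome but shallow enough
that detection and rank-based pathway scores vary visibly between
replicates. `pathrepro` implements the full analysis needed to answer it:
gene-level TPM construction from Salmon quantifications, two single-sample
pathway scoring methods, and an exhaustive replicate-combination scheme
that turns a gene × replicate TPM matrix into reproducibility curves.

## What it computes

Both scoring methods read a sample only through ascending midranks
$r_g$ (highest TPM → rank $N$):

- **ssGSEA** — the summed difference of two ECDFs walked in decreasing
  rank order, in-set genes weighted by $r_g^\alpha$ (default
  $\alpha = 0.25$):
  $ES(S) = \sum_i \big[ P_{\text{in}}(i) - P_{\text{out}}(i) \big]$.
- **singscore** — the set's normalized mean rank,
  $s(S) = \dfrac{\bar r_S - (n+1)/2}{N-n} \in [0, 1]$, directly
  interpretable as a mean percentile rank.

The **combination scheme**: for each $k = 1..n$, every $\binom{n}{k}$
combination of replicates is pooled (TPM summed), filtered (TPM < 0.1
removed), and scored against a pathway collection (GMT, sets with < 5
genes dropped); the Spearman correlation of pathway-score vectors is
computed for all $\binom{\binom{n}{k}}{2}$ pairs of size-$k$ combinations
and summarized per $k$ as median ± IQR. The same machinery with a union
rule over detection calls yields detection-saturation curves, and
replicate-level statistics (per-gene CV, pairwise Spearman, cross-platform
mean-rank Pearson) characterize the platforms themselves.

A calibrated synthetic generator (log-normal abundances, depth-limited
Poisson sampling with emergent dropout, per-replicate log-normal noise,
injectable pathway activation) stands in for sequencing data, so the whole
pipeline runs and is tested without downloads. See the vignette in
`vignettes/pathway-score-reproducibility.Rmd` for the models, calibration
and design decisions.

## Worked example

Simulate an ONT-like experiment (five replicates at 1.5 M reads, 10,000
genes, 200 pathways) and ask how reproducible singscore pathway calls are:

```r
library(pathrepro)

cfg  <- synthetic_config(seed = 7)
sim  <- simulate_experiment(cfg)
sets <- filter_collection(sim$catalog$pathways, min_genes = 5)

cv_report(sim$matrices$ONT)
#> Coefficient of variation: 7845 genes x 5 replicates (ONT)
#>   median CV = 37.02%

rr <- reproducibility_analysis(sim$matrices$ONT, sets, method = "singscore")
rr
#> Pathway-score reproducibility (singscore, 5 replicates, 200 pathways, ONT)
#> # A tibble: 4 × 4
#>       k median     iqr     n
#>   <int>  <dbl>   <dbl> <int>
#> 1     1  0.842 0.0218     10
#> 2     2  0.922 0.0301     45
#> 3     3  0.951 0.0241     45
#> 4     4  0.970 0.00946    10
```

Reading: across the 10 pairs of single replicates the median Spearman
correlation between pathway-score vectors is 0.84 — noticeably unstable —
while pooling any two replicates lifts it to 0.92 and the curve flattens
beyond that. Two replicates is where the marginal gain collapses, for this
depth and noise level. `autoplot(rr)` draws the boxplot version;
`tidy(rr)` returns the 110 individual pairs;
`saturation_analysis(sim$matrices$ONT)` gives the detected-gene analogue.

Real data enters through `read_salmon_quant()`,
`build_tx2gene_from_gtf()` (protein-coding + `basic`-tag + standard
chromosome filters), `build_expression_matrix()` and `read_gmt()`. A thin
command-line wrapper with the same defaults lives at
`inst/cli/pathrepro.R` (subcommands `aggregate`, `score`, `saturate`,
`repro`, `simulate`).

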