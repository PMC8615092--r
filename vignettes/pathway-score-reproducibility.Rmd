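---
title: "How many replicates for stable single-sample pathway scores?"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How many replicates for stable single-sample pathway scores?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathrepro)
library(dplyr)
```

## The problem

Nanopore direct RNA sequencing reads native RNA molecules without reverse
transcription or amplification, but a single MinION flow cell yields on the
order of one to two million mapped reads — one to two orders of magnitude
below a typical short-read run. At that depth, low-abundance genes drop out
of any single replicate, and the question for anyone planning an experiment
is practical: **how many replicates are needed before downstream summaries
— detected-gene counts and single-sample pathway activation scores — become
stable?**

`pathrepro` answers this with an exhaustive combination scheme. Given a
gene-by-replicate TPM matrix, it forms *every* combination of $k$
replicates for $k = 1, \dots, n$, pools each combination into a
pseudo-sample, scores a pathway collection on each pooled sample, and
computes the Spearman correlation of the pathway-score vectors for every
unordered pair of distinct size-$k$ combinations. The per-$k$ distribution
of these correlations — summarized as median and IQR — is the
reproducibility curve; the smallest $k$ where it plateaus is the replicate
requirement. An analogous union rule over detection calls gives the
detection-saturation curve.

## The two scoring models

Both scores consume a single sample's expression vector and a gene set
$S$, and both depend on expression only through ascending midranks $r_g$
(ties get the mean of the positions they span, highest expression gets
rank $N$). That rank-invariance is load-bearing: it makes the scores
insensitive to any strictly monotone distortion of TPM, which is exactly
the kind of difference one expects between platforms.

**ssGSEA.** Walking the genes in decreasing rank order, the score is the
summed difference between a rank-weighted ECDF of the in-set genes and an
unweighted ECDF of the out-set genes:

$$ES(S) = \sum_{i=1}^{N}\left[
   \frac{\sum_{j \le i,\; g_j \in S} r_{g_j}^{\alpha}}
        {\sum_{g \in S} r_g^{\alpha}}
 - \frac{\left|\{j \le i : g_j \notin S\}\right|}{N - |S|}\right].$$

The exponent defaults to $\alpha = 0.25$ and the score table is divided by
its global max−min range, matching the defaults of the widely used GSVA
implementation. Whether that normalization is on or off is immaterial
here: it is one positive global rescaling, so every Spearman-based
comparison is unchanged. A useful closed form used in the tests: a
singleton set containing the top-ranked gene scores exactly $N/2$ for any
$\alpha$.

**singscore.** The normalized mean rank of the set,

$$s(S) = \frac{\bar r_S - (n+1)/2}{N - n},$$

with $n = |S \cap \text{universe}|$. The denominator maps the attainable
range onto $[0,1]$ exactly — the bottom-$n$ set scores 0 and the top-$n$
set scores 1 — so the value reads directly as a normalized mean percentile
rank. Only unidirectional sets are supported: pathway GMT collections in
the WikiPathways style carry no up/down annotation.

Degenerate sets (no member in the sample's universe, or all of it) have no
defined score; they propagate as `NA` and are dropped pairwise in
downstream correlations.

## From quantifications to the matrix

The pipeline consumes transcript-level Salmon `quant.sf` tables. Gene
expression is the sum of the member transcripts' TPM — TPM is relative,
so summation conserves the total. The transcript-to-gene map comes from an
Ensembl GTF restricted to feature type `transcript`, `gene_biotype` and
`transcript_biotype` both `protein_coding`, the `basic` tag, and standard
chromosomes (1–22, X, Y, MT by default; the non-standard set is not
enumerable in general, so the chromosome list is configurable). One
parsing subtlety: the `tag` attribute key legitimately repeats within a
GTF record, and generic readers keep only one value per key, which would
silently drop transcripts from the `basic` filter — the package therefore
extracts the four needed attributes with targeted regexes and accepts both
`key "value";` spacings.

Two thresholds recur. **Detection** is TPM strictly above 0 (a Salmon
target with no reads reports exactly 0). **Low-expression filtering**
removes genes with TPM strictly below 0.1, applied per scored sample
*after* pooling — the literal reading of the processing order, so at
larger $k$ the summed vector clears the threshold more easily. Passing
`pool = "mean"` divides pooled values by $k$, making the threshold
depth-invariant; the tests verify that sum-pooling at threshold $k\cdot t$
and mean-pooling at $t$ give bitwise-identical results, as they must for
rank-based scores.

Pathway collections are filtered once, globally: sets with fewer than 5
genes are dropped, counted on the raw set rather than on any intersection
with an expression universe, because the size filter is an
annotation-level decision taken before any sample is seen.

## Replicate-level statistics

For platform characterization the package reports, per platform and
restricted to genes detected in every replicate: the per-gene CV
($100\cdot\text{sd}/\text{mean}$, sample standard deviation) with its
median; the pairwise Spearman correlation matrix between replicates; and,
across platforms, the Pearson correlation of mean gene ranks, where each
replicate is ranked over its platform's full universe (undetected genes
carry TPM 0 and tie at the bottom) and genes detected in only one
platform are excluded from the correlation but returned as explicit lists
— they are the marginal "spurs" of a rank–rank scatter plot. A flag
(`include_exclusive`) adds them back, since reasonable analysts could read
the convention either way.

Quartiles everywhere use linear interpolation between order statistics
(`stats::quantile` type 7). This matters: IQR values quoted to two or
three decimals are not comparable across quartile conventions.

## The combination scheme's accounting

With $n$ replicates there are $\binom{n}{k}$ combinations of size $k$ and
$\binom{\binom{n}{k}}{2}$ pairs — for $n=5$: 10, 45, 45, 10, 0 pairs at
$k = 1..5$; for $n=3$: 3, 3, 0. Pairs at $k \ge 2$ overlap in members
(e.g. (1,2,3,4) vs (1,2,3,5)), which inflates correlations at large $k$;
this is deliberate, as it mirrors how the scheme is defined, and a
`disjoint_only` option restricts to member-disjoint pairs for sensitivity
checks at small $k$. The size-$n$ "combination" has no partner and
contributes detection counts but no correlation. No randomness is
involved anywhere in the scheme — it is exhaustive, not sampled.

## What the synthetic generator emulates

There is no public ground truth for a cell line's transcriptome at this
granularity, so the package ships a generative stand-in (labelled
synthetic throughout) whose purpose is to reproduce the *statistical
shape* the analysis cares about:

* **Abundance:** i.i.d. log-normal with sdlog 2.2 — a heavy-tailed
  dynamic range of roughly five orders of magnitude, typical of bulk
  transcriptomes. The meanlog is irrelevant (abundances are normalized
  before sampling).
* **Depth and dropout:** read counts are Poisson at
  $\text{depth} \times \text{normalized rate}$; TPM is the count scaled
  to $10^6$ (each replicate's TPM sums to exactly $10^6$ by
  construction). Dropout is emergent: at the ONT-like default of 1.5
  million reads a substantial fraction of low-abundance genes receives
  zero reads, while at the Illumina-like 50 million nearly everything is
  seen. The defaults bracket the mapped-read counts of real runs of each
  platform type.
* **Replicate noise:** a per-gene log-normal factor
  $\exp\!\big(\mathcal N(0, \sigma^2)\big)$ redrawn each replicate, with
  $\sigma = 0.33$ (ONT-like) and $0.26$ (Illumina-like). Combined with
  Poisson sampling this puts the median per-gene CV in the mid-30s and
  low-20s percent respectively — the right regimes for the two platform
  classes. The Poisson–log-normal compound is already overdispersed
  relative to Poisson; a negative-binomial dispersion knob was considered
  and left out as redundant at these calibrations.
* **Pathways:** uniform random gene subsets, 200 sets of 10–100 genes by
  default — the size range spans typical curated pathway collections
  after the min-5 filter. Uniform sampling means pathway genes are
  abundance-unbiased, unlike curated pathways, which skew toward
  well-expressed genes; observed score reproducibility on real
  collections is therefore likely somewhat *higher* than on synthetic
  ones at equal depth.
* **Activation:** multiplying member-gene abundances by a fold factor
  injects a known signal, enabling recovery tests (injected pathways
  should dominate the score difference between an activated and a
  baseline run). Supplying the same config with a modified catalog reuses
  the same sub-seed stream, pairing the sampling noise between the two
  runs.

What the generator does **not** emulate: gene length effects (TPM is
simulated directly), isoform switching, sequence-composition biases,
batch structure, and correlated gene–gene noise. Transcript-level
structure exists only as random per-gene shares so the aggregation step
can be exercised end-to-end. Passing tests on synthetic data therefore
demonstrate the *pipeline's* correctness and the qualitative
depth-reproducibility relationship, not quantitative agreement with any
particular experiment.

Everything is deterministic given the config seed: the catalog draws use
the seed directly and replicate sub-seeds are drawn from an offset stream,
so adding profiles or replicates never silently reshuffles earlier ones.

## Numerical choices and degenerate inputs

* Ties are midranked everywhere; within ssGSEA's decreasing-rank walk,
  tied genes are visited in input order (`order()` is stable). The ECDF
  sum is computed with cumulative sums; the test suite checks it against
  an explicit per-step double-loop evaluation to $10^{-9}$ over all
  subsets of small universes.
* Spearman is computed as Pearson on midranks of pairwise-complete
  entries; fewer than 3 complete pairs, or a constant vector, yield `NA`
  rather than an error, and `NA`s are dropped (and counted) before
  median/IQR summaries.
* An empty result is an error, not an empty object, at the points where
  continuing would silently produce nonsense: no genes past the
  expression filter, no sets past the size filter, all scores missing.
* Matrix TSVs are written with 6 significant digits; re-writing a file
  the package wrote reproduces it byte for byte, which keeps round-trip
  tests exact.

## Problem sizes

The shipped tests run the full scheme at the generator's native scale —
10,000 genes, 200 pathways, five ONT-like and three Illumina-like
replicates, ten seeds for the statistical properties (pooling
monotonicity, platform contrast, activation recovery) — which completes
in well under a minute per property on a single core; unit tests use toy
fixtures of tens of genes where hand computation is possible. The
`scripts/acceptance.R` study uses the same native scale.

## Known limitations

* The replicate requirement the synthetic study yields is conditional on
  the generator's calibration; for a new platform or protocol, re-fit
  `depth` and `noise_sd` to a pilot CV estimate before trusting the
  curve.
* Only unidirectional gene sets are scored; directional (up/down)
  signatures would need a signed extension of both engines.
* Pooling operates on TPM tables, not reads; it emulates added depth
  exactly only under the relative-abundance model TPM implies.
* Overlapping combinations make per-$k$ correlation distributions
  dependent; the median is a fair summary, but the pairs are not
  independent samples and should not feed significance tests as if they
  were.
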