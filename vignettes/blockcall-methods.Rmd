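---
title: "Haplotype-block-guided genotype calling from low-coverage sequence data"
author: "blockcall package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-block-guided genotype calling from low-coverage sequence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockcall)
```

## The problem

Whole-genome sequencing of large plant breeding panels is usually run at
very low depth (around 0.5X) to keep costs down. At 0.5X, roughly
$1 - e^{-0.5} \approx 39\%$ of genotype-matrix cells receive at least one
read; the rest are missing and must be imputed. For fully homozygous
material — doubled-haploid (DH) lines carry a single haplotype genome-wide,
so no phasing is needed — there is an additional source of information that
generic imputation software ignores: long stretches of the genome are
shared identical-by-descent (IBD) between lines descending from the same
founders. If a group of lines is locally identical, their reads at a marker
are exchangeable, and pooling them turns many 0–1 read cells into cells
with dozens of supporting reads.

`blockcall` implements this block-guided calling step: given a raw variant
panel (genotype calls plus per-allele read counts from a VCF) and a
haplotype-block library describing local group-wise IBD, it

1. merges reads across block neighbors with a self-weight on the line's own
   reads,
2. re-calls genotypes by a weighted consensus rule,
3. re-inserts raw calls where no consensus is reached,
4. estimates a per-cell read-depth and filters low-quality markers, and
5. optionally calls copy-number variants (CNVs) from kernel-smoothed depth
   ratios.

A window-based block finder, a DH-population simulator and the evaluation
statistics used to benchmark the step complete the package, so every stage
is testable at desk scale without any external dataset.

## The model

### Read merging and consensus calling

Let $r_a(h, m)$ be the raw read count supporting allele
$a \in \{\mathrm{REF}, \mathrm{ALT}\}$ for haplotype $h$ at marker $m$, and
$N(h, m)$ the union of the members of every block containing $h$ and
covering $m$ (minus $h$ itself). The weighted support is

$$ w_a(h, m) = s \cdot r_a(h, m) + \sum_{g \in N(h,m)} r_a(g, m), $$

with self-weight $s = 5$ by default. Only reads participate; calls asserted
without read support (for instance imputed upstream) contribute nothing.
The cell is called to allele $a$ iff

$$ \frac{w_a}{w_{\mathrm{REF}} + w_{\mathrm{ALT}}} \ge 0.8
   \quad\text{and}\quad w_{\mathrm{REF}} + w_{\mathrm{ALT}} > 0, $$

and left missing otherwise ("at least 80%", so a share exactly at the
threshold counts). Consensus calls take precedence over raw calls — this is
the error-correction mechanism: with one own read ($s \cdot 1 = 5$ weighted)
an overwrite requires opposing neighbor reads of at least $4 \times 5 = 20$,
i.e. overwriting demands much stronger evidence than calling a previously
missing cell. Where no consensus is reached, the raw call is re-inserted so
rare variants carried by a single line are never lost. Cell provenance
(`RAW_CALLED` / `HB_CALLED` / `COMPLETED` / `MISSING`) is tracked so that
error rates can later be stratified by how each call arose.

The self-weight trades error correction against the ability to detect
recent or rare variation private to one line: $s \to \infty$ reduces the
method to the raw caller, $s = 1$ lets large blocks overrule even unanimous
own reads. The default of 5 keeps a single own read decisive unless
neighbors oppose it 4:1 in reads.

### Depth estimation and marker filters

The per-cell depth estimate divides weighted reads by the weighted
haplotype count,

$$ \hat d(h, m) = \frac{w_{\mathrm{REF}} + w_{\mathrm{ALT}}}{s + |N(h, m)|}, $$

so that in expectation it stays on the scale of the sequencing depth
regardless of block size. Cells covered by no block get no estimate
(`NA`); they still keep their own self-weighted reads for calling, so an
isolated line degenerates gracefully to its raw data. The run summary also
reports the mean *weighted read count* per covered cell — the
"average read-depth" a pipeline reports after merging, which deliberately
counts the line's own reads $s$ times.

Two conservative marker filters follow, both evaluated in one pass against
the pre-filter overall mean (so their order cannot matter, which the test
suite asserts): a marker is dropped when its mean estimated depth over
covered cells is strictly below 50% of the overall mean, or when strictly
more than 50% of its calls are missing. Markers with no covered cell have
no depth estimate and are exempt from the depth filter (they usually fall
to the missingness filter instead); this situation does not arise when the
block library covers the panel reasonably well.

### CNV calling

Read-depth per marker is far too noisy at low coverage to threshold
directly, so the depth track is first smoothed along the genome with a
Nadaraya–Watson estimator,

$$ \tilde d(x_j) = \frac{\sum_i K\!\left(\frac{x_j - x_i}{b}\right) \hat d(x_i)}
   {\sum_i K\!\left(\frac{x_j - x_i}{b}\right)}, \qquad K(u) = e^{-u^2/2}, $$

evaluated at marker positions only, with gaps excluded from both sums and
no smoothing across chromosome boundaries. The bandwidth $b$ (default
0.25 Mb) is interpreted as the standard deviation of the Gaussian kernel —
the most common convention; smaller bandwidths target shorter CNV
segments. The smoothed individual track is compared to the population
average depth (total raw reads over number of haplotypes, per marker):
ratio strictly above 1.3 is classified as a duplication, strictly below
0.7 as a deletion. Maximal runs of same-label markers merge into one CNV
call; a run is terminated by any cell without a depth estimate (gaps do
not bridge — region merging rules are a documented choice here, the
method itself prescribes none). Calls can be appended to the panel as
binary pseudo-markers (carrier = 1), flagged as non-SNP.

Because the individual track is self-weighted while the population average
is raw, absolute ratios are inflated on real-scale data; the
`standardize = TRUE` option divides each track by its genome-wide mean
first and is recommended outside toy settings. The unstandardized ratio is
the normative arithmetic of the worked 5-haplotype example
(`toyExample()`), where the classification is exercised without smoothing:
estimated depths 0.857X for the two read-carrying block members versus a
0.4X marker average give ratio 2.14 (duplication), and the uncovered pair
with depth 0 gives ratio 0 (deletion).

### The block library

A haplotype block is a marker interval plus the set of haplotypes whose
sequences over the interval are identical; blocks may overlap both in
markers and members, and all queries take unions over covering blocks.
Libraries are interchanged as a TSV (1-based inclusive marker indices,
comma-separated member lists) and held internally in 0-based half-open
coordinates; base-pair positions stay 1-based as in VCF, and the BED
export converts explicitly — one conversion site per dialect.

The bundled finder (`findBlocksWindowed`) is deliberately simple plumbing,
not a reimplementation of an adaptive haplotype-library algorithm: it
groups haplotypes with exactly identical sequences within fixed
20-marker windows, keeps groups of at least 3 members, and merges blocks
of adjacent windows with identical member sets. Exact identity (no
mismatch tolerance) keeps the finder brute-force checkable and its output
deterministic (blocks sorted and numbered by chromosome, start and member
set, so repeated runs are byte-identical). Real libraries from a
dedicated tool can be supplied via the TSV instead; extra reference
haplotypes in the library are accepted, they simply contribute reads.
Panels carry a per-chromosome marker index assigned at construction and
preserved under subsetting, so a library stays valid after marker
filtering.

## The synthetic data generator

`simConfig()` / `simulatePopulation()` emulate the study design the
method targets: a panel of DH lines derived from a modest number of
founders, sequenced at 0.5X. Defaults (chosen once, as a realistic
desk-scale rendition of such a panel): 10 founders, 200 lines, 2,000
markers on one 200 Mb chromosome, founder ALT frequencies uniform on
[0.1, 0.9], one expected crossover per line (long IBD segments, so
founder groups of about 20 lines carry each local haplotype), read counts
Poisson with mean 0.5, a 1% per-read miscall rate, and optional CNV
events that scale the local Poisson mean for a random carrier subset of
lines. Raw calls are the majority allele per cell, missing on zero reads
or ties — a simple surrogate for the upstream caller, to which the block
step is agnostic. Everything is deterministic given the config seed.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: founder linkage disequilibrium beyond mosaic
sharing (founders are drawn independently per marker), mapping artifacts
and reference bias, marker ascertainment, genotyping batch effects, and
CNV carriers aligned with haplotype background. The last point matters
for the depth benchmark: real CNVs segregate with their haplotype, so
block pooling *reinforces* their depth signal, whereas the generator's
random carriers make pooling attenuate it; the benchmark is therefore a
conservative test of the depth-tracking contrast.

Simulated traits place 10 equal-effect QTLs on markers with minor allele
frequency at least 0.1 and add Gaussian noise scaled so the genetic
variance share equals the target heritability (default 0.5).

## Evaluation statistics

* **Discordance**: fraction of compared cells where two panels disagree,
  overall and stratified by cell provenance and by the comparison panel's
  allele (asymmetries between REF and ALT error rates live on the
  allele-calling side, so strata are keyed on the comparison call). Cells
  missing in either panel are excluded.
* **Imputation accuracy**: per-marker Pearson correlation of 0/1 codes,
  averaged over markers polymorphic in the comparison panel, with
  zero-variance markers contributing 0. Averaging per marker rather than
  pooling cells is what gives rare variants their heavy weight in this
  metric.
* **Allele-frequency spectrum**, **CNV recall / false-positive share**, a
  minimal **single-marker regression scan** (no kinship correction, no
  multiple-testing machinery — thresholds are swept externally), and
  **GWAS region classification**: significant markers at most 1 Mb apart
  chain into regions; a region is a true positive iff a QTL lies within
  1 Mb of its interval (distance 0 if inside); for hit QTLs the distance
  from the region's p-value peak to the QTL is the fine-mapping statistic.

## Numerical and design choices

* Calls are integer-coded (0 = REF, 1 = ALT, `NA` = missing) in
  markers-by-haplotypes matrices inside a `SummarizedExperiment`-derived
  container.
* Strict versus weak inequalities follow the rule definitions: consensus
  share is $\ge$, depth and missingness filters and CNV ratio thresholds
  are strict.
* Consensus ties are impossible (the share threshold must exceed 0.5);
  completion ties break neighbor-majority → population-majority → REF.
* Heterozygous handling: diploid homozygous genotypes collapse to one
  haplotype row; unphased heterozygous genotypes become missing (they are
  also what the 1%-heterozygosity ingest filter screens); phased input
  splits each sample into two rows, both receiving the cell's full read
  counts, since a VCF does not say which haplotype generated a read.
* Internal depth values are kept exact (2/7, 6/7); only display output
  rounds.
* The benchmark in the acceptance suite compares the block pipeline
  (merge → consensus → filter → naive completion) against the
  block-*agnostic* completer on the same data — the relevant contrast,
  since a block-aware completer on IBD-exact synthetic blocks is already
  nearly equivalent to the full pipeline at these block sizes (about 20
  members yield about 10 opposing reads, below the 20 needed to overwrite
  an own-read call, so error correction by overwriting only bites with
  larger blocks than this population provides).

## Problem sizes

The test and acceptance suites run entirely on generated data: the
5-haplotype worked example, randomized oracle instances up to a few
hundred markers, and one seeded benchmark population of 200 lines by
2,000 markers at 0.5X with four injected CNV events (two duplications
at multiplier 2.0, two partial deletions at 0.3, carrier fraction 0.2,
about 10 Mb each). These sizes were chosen so each stage's behavior is
measurable while the whole suite completes in well under a minute of
compute for the unit tests plus a few seconds for the benchmark.

## Known limitations

* The finder requires a complete auxiliary matrix and exact identity; it
  will fragment blocks in diverse material where a similarity-tolerant
  library would not.
* CNV classification only sees depth at VCF marker positions; it cannot
  detect copy-neutral variation (inversions, translocations) or events
  between markers.
* With two haplotype rows per heterozygous sample, read apportioning
  between haplotypes is unknowable from a VCF, so per-haplotype depth is
  overstated for such input.
* The naive completer is plumbing for end-to-end tests, not a substitute
  for a dedicated imputation tool on real data.
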