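---
title: "serascan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{serascan: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serascan)
```

## The problem

Fetal bovine serum (FBS) is close to universal in cell culture, and it
carries its own RNA — much of it evolutionarily conserved and therefore
indistinguishable from host transcripts by annotation. When
extracellular RNA (exRNA) is sequenced from conditioned media, bovine
reads co-purify with the cell-derived material, and even
vesicle-depleted serum preparations retain most of their RNA. serascan
quantifies this contamination from sequencing reads alone.

The core statistic is the **contamination index**

$$ r = \frac{n_{\text{specific-B}}}{n_{\text{specific-A}}}, $$

where a read is *specific* to a genome if it aligns to that genome and
not to the other under a competitive dual-reference classification
(A = host, e.g. human; B = contaminant, e.g. bovine). Normalising the
contaminant-specific count by the host-specific count, rather than by
library size, cancels sample-to-sample variation in mappability and
depth. Under the idealisation that cross-species mapping is symmetric,
the index inverts to a contaminant read fraction
$\hat c = r / (1 + r)$; symmetry holds well in practice because reads
mapping to *both* genomes are excluded from both specific counts in
proportion, which is also why $\hat c$ recovers the simulated fraction
to within a few thousandths at 0.15 divergence even though ~8% of
reads cross-map there.

## Pipeline model

1. **Quality gate.** Per sequencing cycle, the mean PHRED score over
   all reads is computed, and the *optimal read span* is the longest
   uninterrupted run of cycles whose mean strictly exceeds a threshold
   (default Q30; "exceeds" is read as strict, so a flat profile at
   exactly Q30 has an empty span). A dataset whose span is shorter
   than 20 cycles is discarded. The aggregate per cycle is the mean by
   default (the median is available via `stat = "median"`); ties
   between equal-length runs break to the smallest start, which
   preserves 5' sequence where small-RNA signal lives. The span is a
   dataset-level property applied to all reads, not a per-read
   trimmer. Whether reads should be *trimmed* to the span or the span
   used only as a pass/fail filter is left to the caller
   (`trim_reads_to_span()` vs the `trim` flag in the pipeline config;
   both behaviours are exposed because either reading is defensible).
2. **Subsampling.** To put libraries of very different depth on a
   common footing, a uniform random subsample (default $10^6$ reads,
   seeded) is drawn before classification.
3. **Competitive classification.** Each read is aligned independently
   to the two genomes by a seed-and-extend local aligner: every exact
   25-mer of the read (both strands) is looked up in a k-mer index of
   the genome and extended ungapped under +2/−4 match/mismatch scores;
   the best segment containing the seed is kept, and the read is
   *mapped* if its best score reaches `min_score` (default
   `2 × seed_length`, i.e. a perfect 25-base local segment suffices —
   the original tool's length-dependent local threshold is not
   documented, so the package uses this transparent default and
   records it in every report). Categories: `specific_a`,
   `specific_b`, `both`, `neither`; they partition the read set.
   An external-aligner path (`classify_from_alignments()`) applies the
   same categorical logic to the flag fields of two SAM files.
4. **Statistics.** Per-dataset group means ± SEM and the fold change
   (ratio of group means — the only definition consistent with
   reporting means and FC side by side), plus a single global
   two-tailed Mann–Whitney U test across all samples; per-dataset
   testing is avoided because the group sizes (1–6) make it
   meaningless.

## The built-in aligner and its oracle

The simulator emits substitution-only divergence and substitution-only
sequencing errors — no indels. Ungapped extension is therefore exact
for the data the package generates, and the whole classification
contract can be verified against an *exhaustive* oracle: for every
strand, read offset and genome position, test the seed window by
direct character comparison (no index) and extend ungapped with the
identical scoring and tie-breaking rules (score, then lowest genome
start, then + strand, then shortest interval — a total order, so
enumeration order cannot matter). The test suite asserts read-for-read
equality of the two routes on seeded instances, including with
sequencing errors and with 1-mismatch seeds.

A subtlety worth recording: an *unconstrained* ungapped
Smith–Waterman maximum is **not** the right oracle for a seeded
aligner. At 15% divergence a segment scoring above `min_score` with no
exact 25-mer inside it (e.g. 14 matches, 1 mismatch, 13 matches)
occurs in a few percent of reads, so a seedless oracle would disagree
with any seed-requiring implementation. The mapped-predicate is
defined as "has a seed whose ungapped extension reaches `min_score`",
and both routes implement exactly that predicate.

The same arithmetic bounds classification sensitivity. An error-free
host read of length $L = 50$ cross-maps to the contaminant genome
when its homologous window happens to contain $k = 25$ consecutive
matching bases; at per-site identity $p = 1 - d$ the expected number
of such runs is roughly $p^k (1 + (L - k)(1 - p))$, i.e. ~8% at
$d = 0.15$, ~2% at $d = 0.20$ and ~0.5% at $d = 0.25$. A ≥ 99%
specific-A sensitivity is therefore only attainable from about
$d = 0.25$ upwards under the default `min_score`; the property test
uses 0.25. None of this affects the index: cross-mapped reads leave
both specific counts in proportion.

## Statistical conventions

* **Mann–Whitney U.** $U_x$ uses midrank credit for ties; the reported
  statistic is $\min(U_x, U_y)$. When $\binom{n+m}{n} \le 10^5$ the
  permutation distribution of $U_x$ over all group assignments of the
  observed values (ties included) is enumerated and the two-tailed
  exact p is $\min(1,\, 2\min(P(U_x \le u),\ P(U_x \ge u)))$ — the
  convention that reproduces the classic worked examples
  ($\{1,2,3\}$ vs $\{4,5,6\}$: $U = 0$, $p = 2/20 = 0.1$). Larger
  problems fall back to the normal approximation with tie-corrected
  variance and continuity correction, flagged `method = "approx"`.
  Super-uniformity of the exact p under the null is property-tested.
* **t-test.** Pooled-variance unpaired two-tailed t with $n + m - 2$
  df; zero pooled variance with equal means yields $p = 1$ by
  convention.
* **No multiple-testing correction** — a single global comparison is
  performed.

## Composition and qPCR analytics

Counts are normalised to reads per million mapped (RPM; every sample
sums to $10^6$), biotype fractions are RPM sums within annotation
classes, and samples are clustered on $1 - \text{Pearson } r$ between
$\log_{10}(\text{RPM} + 1)$ profiles with average linkage. Base,
pseudocount and linkage are recorded in output metadata and
configurable; average linkage matches the default behaviour of the
external viewers typically used for correlation-based expression
clustering, and Pearson-after-log makes the tree invariant to library
size and feature order. Depletion efficiency is the
pellet/supernatant abundance ratio (from Cq values,
$2^{Cq_s - Cq_p}$).

qPCR quantities follow $RQ = E^{\Delta Cq}$ with efficiency fixed at
2.0 by default (per-gene efficiencies are accepted but standard-curve
estimation is out of scope). geNorm stability is
$M(j) = \text{mean}_k\, \text{sd}_s\!\left(\log_2 q_{js}/q_{ks}\right)$
over candidate references, with the published log2 convention; the
default analysis computes M for a fixed panel (as with a 4-control
panel of U6, U2, miR-103a-3p, miR-24-3p), and the classic iterative
worst-gene elimination is available as `genorm_rank()`. Wells at the
no-amplification ceiling are encoded Cq = 40 and flagged undetected.

## What the synthetic data does and does not emulate

`evolve_genome_pair()` draws an ancestral sequence and substitutes
each site independently at the stated divergence (default scenarios
use 0.15, a reasonable figure for alignable human–bovine sequence).
`simulate_reads()` draws each read's origin Bernoulli($c$), position
uniformly, strand uniformly (minus-strand reads are emitted as
reverse complements; truth coordinates stay forward-strand, 0-based
half-open), applies i.i.d. substitution errors (default $10^{-3}$,
typical of the platform), and samples qualities around a linear 38→28
decay with ±2 integer jitter, floored at 2 — enough 3' decay for the
span rule to be exercised without failing the default gate. Defaults:
50-base single-end reads (matching the 50 bp single-end runs the
method was applied to; read length is otherwise a free choice).

Not emulated: indels, splicing, adapter read-through, paired ends,
non-uniform coverage, and real genome repeat structure. A green test
therefore establishes the correctness of the *procedure* (filtering,
classification logic, index arithmetic, statistics) on a world where
its assumptions hold exactly — it does not certify performance on
real genomes, where repeats and indels make the alignment step
harder and gapped external aligners (via the SAM path) are the
appropriate tool.

`simulate_count_table()` draws multinomial (or Dirichlet-multinomial
for overdispersion) counts around group biotype profiles; the default
profiles give the pellet fraction a miRNA/rRNA excess and the
supernatant an mRNA/snoRNA excess, separated enough (total-variation
distance ≈ 0.3) that correlation clustering must recover the
bipartition. `simulate_cq_table()` models
$Cq = \mu_g + \delta_s + b_{gs} + \varepsilon$ with a shared
per-sample offset $\delta_s \sim N(0, 1)$ (RNA-input variation that
reference normalisation must remove), gene-level biological noise
$b_{gs} \sim N(0, 1.5)$ on non-control genes only (the stable-control
definition), and technical noise (default sd 0.2 Cq).

## Numerical and degenerate-input choices

* RNG: one top-level seed, split deterministically per stage; all
  simulators restore the caller's RNG state. Identical seeds give
  byte-identical FASTQ output.
* PHRED encoding is fixed to +33; out-of-range bytes are rejected
  rather than auto-detected (detection heuristics misfire on trimmed
  data).
* Samples with zero host-specific reads raise a typed
  `serascan_undefined_index` condition and are excluded with a
  warning, never given an infinite index.
* Singleton groups report a blank (NA) SEM; fold changes require a
  positive denominator mean.
* Zero-variance expression profiles make Pearson correlation
  undefined and are reported as errors naming the sample.
* Gzip is detected by magic bytes; tabular output is TSV with
  '#'-prefixed metadata and locale-independent decimals.

## Known limitations

The built-in aligner is deliberately ungapped and single-end; real
data with indels or spliced reads should be aligned externally and
ingested as SAM. The index-to-fraction inversion assumes symmetric
cross-mapping, which can break if one genome is far more repetitive
than the other. Published per-dataset fold changes that do not
reproduce from their own printed rounded means (two of four rows in
the bundled table) are retained in the fixture but excluded from
correctness assertions; they were presumably computed on unrounded
values.
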