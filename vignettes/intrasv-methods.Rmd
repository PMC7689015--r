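---
title: "Methods: comparing intraspecific genome assemblies with intrasv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing intraspecific genome assemblies with intrasv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intrasv)
```

## What the package does

Two assemblies of the same species can differ by tens of megabases:
large insertions dominated by tandem rDNA arrays and LTR
retrotransposons, inverted segments, and diffuse divergence in repeat
content. `intrasv` implements a desk-scale version of the comparative
workflow used to characterise such differences:

1. **Alignment blocks.** Either imported from a whole-genome aligner's
   `show-coords`-style table, or computed internally by
   `anchor_align()`.
2. **Genome-specific regions and inversions** from filtered blocks
   (`filter_blocks()`, `detect_specific_regions()`,
   `detect_inversions()`), with per-region content summaries
   (`summarize_region()`, `summarize_table()`).
3. **Repeat landscapes**: windowed density tracks, per-chromosome TE
   order proportions, and chi-square homogeneity tests.
4. **Copy numbers of repeat families** by read depth calibrated on
   single-copy genes (`cluster_sequences()`, `build_consensus()`,
   `map_reads_depth()`, `estimate_family_copy_numbers()`).
5. **Repeat phylogenies**: alignment trimming, Jukes–Cantor distances,
   neighbor joining, bootstrap supports, long-branch pruning.
6. **Genome size** from flow-cytometry G1 peaks, with one-way ANOVA,
   Tukey HSD letters and a Shapiro normality check.

A synthetic-data module (`simulation_config()`,
`simulate_genome_pair()`, `simulate_reads()`) generates a diverged
genome pair with planted ground truth so that every detector can be
scored against known answers without any external download.

## Coordinate conventions

Alignment blocks, specific regions, inversion calls and BED output are
0-based half-open; conversion to and from 1-based inclusive happens
only at file boundaries (`show-coords` tables, GFF3). Annotations keep
GFF3's native 1-based inclusive convention, since that is how every
consumer of GFF3 expects them. Reverse-orientation blocks are
normalised on read so that `qry_start < qry_end` always holds, with
orientation carried separately; this preserves block length on both
genomes.

## The anchor aligner

`anchor_align()` stands in for a whole-genome aligner at desk scale.
k-mers (default `k = 21`) occurring exactly once in the reference and
exactly once in the query (counting both query strands) become
anchors; anchors sharing a diagonal (forward) or anti-diagonal
(reverse) within `max_anchor_gap` (default 5 kb) are chained, and
chains spanning at least `min_block` become blocks, with percent
identity computed by ungapped column comparison over the span.

Two consequences are worth knowing. First, the chain predicate assumes
no indels *within* a block: substitution-level divergence leaves the
diagonal untouched, while any insertion shifts it and naturally opens a
new block. That matches the simulator (substitution divergence plus
large planted events) and the regime the default filters target
(blocks of ≥ 4 kb at ≥ 95% identity). Real aligner output with small
indels inside blocks should be imported via
`read_alignment_blocks()` instead. Second, uniqueness makes tandem
arrays and multi-copy families anchor deserts; they surface as
uncovered intervals. The `min_region` threshold is what keeps such
repeat islands out of the specific-region calls, so it should sit
above the largest shared repeat array (the defaults: 1 Mb for real
chromosomes, 30 kb in the synthetic acceptance runs whose shared rDNA
array spans 27 kb).

## Specific regions and inversions

A reference interval is *specific* when no block of any comparator
covers it: the union of covered intervals over all comparators is
complemented per chromosome; complement intervals separated by covered
stretches shorter than `merge_gap` merge; merged intervals of at least
`min_region` are reported. The implementation is interval arithmetic
on `IRanges`, and the test suite pins it against a brute-force
per-base oracle on fuzzed instances up to 100 kb.

Inversions are reverse-orientation blocks chained while reference
coordinates increase, query coordinates decrease and consecutive
blocks stay within `chain_gap` (default 100 kb) on both genomes.
Isolated reverse blocks are reported as single-block calls, since
real inversion catalogues extend down to tens of kilobases.

Region summaries count a feature on ≥ 1 bp overlap and clip
cumulative lengths to the region. GC% keeps N bases in the
denominator — the convention that reproduces published N-rich region
tables — and the headline statistics follow the reporting conventions
of such tables: bp statistics truncated toward zero, count and percent
statistics at two decimals, even-count medians as midpoints.

## The simulator as study conditions

Genome A is an ancestral genome (default: two 1-Mb chromosomes at 36%
GC) carrying 20 single-copy genes of 1 kb, a TE library of four
families, and a tandem rDNA array (9-kb unit — the canonical size of a
plant 45S unit — 3 copies). Genome B applies a SNP overlay at 1%
divergence *before* structural events, so inverted and flanking
sequence carry the same background divergence and stay inside the
≥ 95% identity filter regime; then two inversions (80 and 60 kb) and
three insertions (50, 120 and 200 kb) composed of tandem rDNA units,
surplus TE copies and random filler. TE copies mutate independently at
2% per copy so that a family clusters at the 90% identity threshold.

Reads are single-end, fixed length (100 bp), substitution errors only
(default 1%), drawn from both strands with uniform starts —
`floor(coverage × genome / read_length)` of them. Indels,
quality-score structure, GC bias and heterozygosity are deliberately
absent: the mapper is ungapped and the claims the tests make are about
the detectors' logic, not about robustness to sequencing artefacts.
Passing on this generator therefore demonstrates correctness of the
block/coverage/depth arithmetic under clean divergence, and says
nothing about, for example, indel-rich alignments or diploid genomes.

The copy-number study conditions (`cnv_study_config()`) plant four
families at 1, 5, 20 and 50 copies with 24 calibration genes on a
200-kb chromosome read at 20×. Consensus lengths are graded (1.5 kb
down to 550 bp, longer for low-copy families) so each family collects
enough reads for a stable depth: at these sizes the per-family
sampling error is 2–4%, comfortably inside the ±10% recovery band.

## Copy-number estimation

Repeat copies cluster by single linkage on global-alignment identity
(> 90%), each cluster gets a center-star majority consensus
(alphabetical tie-break, columns with > 50% gaps dropped), and reads
map to the consensus set together with the single-copy genes by exact
k-mer seeding at several offsets on both strands followed by ungapped
extension; a read counts toward the reference(s) with the fewest
mismatches (≤ 10% of the read), ties split fractionally. Calibration
is the *median* of per-gene depths — robust to the occasional
mis-annotated multi-copy gene.

One numerical subtlety: with full-containment mapping, a reference of
length `L` only accepts reads starting at `L − read_length + 1`
positions, so raw mean depth (`aligned bp / L`) is attenuated by
`(L − read_length + 1)/L` — differently for references of different
length. The reported `mean_depth` keeps the plain definition, but the
copy-number ratio uses effective-length depths
(`aligned bp / (L − read_length + 1)`), which makes the
calibration-gene self-test exactly 1.0 and removes a length-dependent
bias of up to ~6% at the study scale.

## Phylogenies

Alignment trimming first strips end columns while residue presence is
strictly below 25% (a column at exactly 25% survives this rule), then
removes remaining columns with gap fraction strictly above 25%. Note
the composition: an end column at exactly 25% presence has 75% gaps
and is therefore removed by the second rule; the end-rule boundary is
observable by disabling the gap filter.

Jukes–Cantor distances use pairwise deletion — repeat alignments are
gappy enough that complete deletion can empty a matrix — and saturated
pairs (`p ≥ 0.75`) receive a finite, configurable cap (default 5.0)
with a warning rather than failing. Neighbor joining is the standard
Q-criterion agglomeration (via `ape::nj`); any negative branch length
is clamped to zero with the deficit moved to the adjacent branch, so
reported branch lengths are non-negative while path lengths through
the affected node are preserved. Bootstrap supports resample columns
with replacement and count bipartitions of the original tree among
replicate trees; the whole procedure is deterministic given a seed.
Long-branch pruning removes leaves whose terminal branch exceeds 10×
the median terminal branch (an invented but conventional rule — no
published threshold exists) and rebuilds, at most twice.

## Genome size statistics

1C content is the G1-peak ratio times the standard's 1C value (default
4.45 pg, a garden-pea internal standard — a required parameter, since
published workflows rarely print the value they used), and genome size
is `1C × 978 Mbp/pg`; that constant reconciles the published
pg-and-Mbp pairs this package's acceptance values are checked against.
Headline percent differences round to integers.

ANOVA, the Shapiro test and Tukey HSD are the classical procedures
(`oneway.test`, `shapiro.test`, `TukeyHSD` under the hood). The Tukey
default is the analytic studentized-range distribution — R provides
it, and it matches how such analyses are actually run in R — with a
seeded permutation flavour (`method = "permutation"`, pooled-residual
resampling of the max studentized range) available for users who
prefer a distribution-free variant. Compact letters come from the
usual insert-and-absorb sweep, so accessions sharing a letter are
never significantly different at the chosen level.

## Determinism and problem sizes

Every stochastic step takes an explicit seed (`simulation_config()`,
`simulate_reads()`, `bootstrap_support()`, `tukey_groups()`), and the
pipeline summary records all seeds and every parameter's provenance
(default vs config). The test suite and the acceptance script run the
full machinery at the sizes above — 2 × 1 Mb for structural recovery,
200 kb at 20× for copy numbers, 100 random additive matrices up to 12
taxa for the neighbor-joining oracle, 5,000 simulated homogeneous
tables for the chi-square type-I check — sizes chosen so the whole
suite completes in a few minutes on one CPU while leaving each
statistical check enough replication to be meaningful.

## Known limitations

- The anchor aligner is ungapped within blocks and unique-anchor based:
  segmental duplications alias to anchor deserts, and indel-rich
  divergence fragments blocks. Import real aligner output for such
  genomes.
- The read mapper requires full containment and substitution-only
  alignment; it is not a general-purpose mapper.
- Copy numbers are per consensus; what a "unit" means (a full tandem
  repeat unit vs a subsequence) is defined by the repeat library the
  user supplies.
- Clade counting on repeat phylogenies, GO enrichment, cytogenetic
  validation and TE annotation itself are out of scope; the package
  consumes GFF3 annotations, it does not produce them.
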