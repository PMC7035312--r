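---
title: "Methods: single-sperm scRNA-seq QC, differential expression and cell-resolved variant burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-sperm scRNA-seq QC, differential expression and cell-resolved variant burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, parameter choices and numerical
conventions behind `scsperm`, in the spirit of a methods section: what each
stage assumes, which knobs matter, and what the synthetic data can and
cannot tell you about real sperm sequencing.

## Why sperm is a special case

Mature spermatozoa retain roughly 50 fg of fragmented RNA — two to three
orders of magnitude less than a typical somatic cell — concentrated in a
few transcripts, with the protamines (PRM1, PRM2) at the top. Droplet
scRNA-seq of sperm therefore yields tens of thousands of barcodes whose
libraries hold tens, not thousands, of UMIs. Two consequences shape the
package:

* **QC thresholds are tiny.** The defaults — at least 25 UMI and 10
  detected genes per cell, at most 40% mitochondrial UMI, genes detected in
  at least 20 retained cells — would discard nothing in somatic data but
  bisect a sperm experiment.
* **Cells are haploid.** Each cell carries exactly one allele per site, so
  a per-cell variant caller can treat a cell's majority base as its
  genotype, and "number of supporting cells" is a meaningful measure of a
  variant's prevalence in the sperm population, including mosaic variants
  restricted to a stem-cell lineage.

## QC cascade

`filter_cells_genes()` evaluates all three cell rules on the **original**
matrix (a cell is kept iff `n_umi >= 25`, `n_genes >= 10`,
`pct_mito <= 40`), then applies the gene rule once to the surviving cells
(`detected in >= 20 retained cells`, where detected means count > 0). The
boundaries are exactly as quoted in the conventions above: values *at* the
threshold are kept, values strictly beyond are removed. The cascade is a
single pass and is not iterated: gene removal never feeds back into cell
metrics. A re-run on its own output removes no further cells — only genes
whose detection count fell when cells were removed — and reaches a fixed
point by the second application; the test suite asserts this.

The removal log records each removed entity with the *first* failing rule
in the order UMI → genes → mitochondrial fraction, a reporting convention
only (retention is conjunctive and order-free).

Subsampling (`subsample_cells()`) draws uniformly without replacement under
an explicit seed. When a sample holds fewer cells than the target (the
study convention is 12,000 per sample, which desk-scale synthetic samples
never reach), all cells are kept and a warning raised; silently sampling
with replacement or failing would both misrepresent the experiment.

## Normalization and differential expression

Counts are normalized per cell to a common depth and log-transformed:
`ln(1 + 10^4 · x / depth)`. The scale factor 10,000 is the convention of
the single-cell toolchain this pipeline mirrors; it is configurable.
All-zero cells stay all-zero rather than becoming NaN.

`wilcoxon_deg()` tests each gene across **all single cells** of the two
cohorts, not across sample means. That choice (the study's own) gives
enormous n and detects subpopulation-driven shifts, at the price of
treating cells as independent; sample identity is retained in the pooled
object so users can inspect per-sample structure. The test is the
two-sided Wilcoxon rank-sum with mid-ranks, the tie-corrected variance
`σ² = n₁n₂/12 [(N+1) − Σ(t³−t)/(N(N−1))]`, and a 0.5 continuity
correction. When the total cell count is at most `exact_max_n` (default
16) the p-value instead comes from exact enumeration of all `C(N, n₁)`
label assignments, which the test suite checks against an independent
enumeration oracle. Bonferroni multiplies by the number of genes actually
tested — i.e. after the marker filter that drops genes expressed in fewer
than 1% of cells of *both* cohorts — so the adjusted threshold matches the
reported list.

Two decisions the source conventions left open, resolved here: the test is
two-sided (the direction of any expression difference is not presumed),
and the default pre-ranked score is the signed average log fold change
(difference of cohort means of normalized expression, case minus control),
with signed −log10 p as an alternative. Ties in the RNK export are broken
lexicographically by gene id so the file is reproducible.

Cross-sample alignment (canonical correlation analysis and related
batch-correction machinery) is deliberately **not** implemented: samples
are pooled after per-cell normalization. Depth normalization removes the
dominant between-sample technical axis in these data; residual batch
structure in real data is a caveat the user must own (see Limitations).

## Per-cell variant calling

The caller is a transparent haploid model rather than a re-implementation
of a general-purpose diploid caller:

1. `regroup_by_barcode()` tallies reads per `CB` tag and drops cells with
   fewer than 100 reads (exactly 100 is kept). Untagged reads are counted
   and discarded; the partition (retained + dropped + untagged = total) is
   asserted in tests.
2. `build_pileups()` expands single-block alignments into per
   (site, cell, base) read counts, excluding bases with Phred quality
   below 13 (≈ 5% error) — a floor low enough to keep coverage in sparse
   data but high enough to suppress the worst miscalls.
3. `call_cell_variants()`: a cell supports an alternative base if it shows
   at least `min_alt_reads_per_cell` (default 1) alt reads **and** the alt
   is the cell's unique majority base — with haploid genotypes the
   majority base *is* the genotype, and a tie means no evidence either
   way. Each site emits at most one call, for the alternative with the
   most supporting cells (then most alt reads, then alphabetical order —
   a deterministic tie-break); other alternatives at multi-allelic sites
   are deliberately not emitted. Site quality is
   `−10·log10 P[Binom(n_total, e/3) ≥ k_alt]` with read counts summed over
   covered cells: the probability that sequencing error alone (rate `e`,
   uniform over the three non-reference bases) produced the observed alt
   support. The tail underflows at high support, so quality is capped at
   3000 — any cap above every working threshold is equivalent.
4. `filter_calls()` keeps calls with quality ≥ 20 supported by ≥ 10 cells
   (≥ 100 in stringent mode). The quality threshold is model-specific —
   numerically analogous, not identical, to an external caller's QUAL at
   the same cutoff.

"Present in a cell" had to be defined (the source conventions leave it
open): at least one alt read with the alt as majority base. With one
anchored read per cell per expressed site, this makes recovery exact on
error-free synthetic data — a planted variant's supporting cells equal
exactly its retained carriers, which the acceptance tests sweep across the
10-cell boundary.

Consequence classification extracts the codon containing the variant from
the CDS (concatenating intervals in genomic order and
reverse-complementing for minus-strand CDS), substitutes the alternative
base, and translates both codons with the standard genetic code. A CDS
whose total length is not a multiple of three, or a variant whose stated
reference base contradicts the reference sequence, is an error, not a
silent skip. Tests verify strand symmetry (a minus-strand CDS classifies
identically to its reverse-complemented plus-strand construct) and
agreement with whole-protein translation before/after mutation.

## Bulk burden statistics

The bulk stage consumes any variant table with alternative-allele depths
(the package's own calls, or an external VCF via `read_vcf_variants()`,
which reads the second field of a FORMAT `AD`). Conventions:

* **SNP clusters:** any run of ≥ 3 SNPs spanning ≤ 35 bp (inclusive span:
  positions 100 and 134 span 35) is removed whole — an RNA-seq alignment
  artifact signature. Input must be coordinate-sorted; unsorted input is
  an error rather than a silent re-sort.
* **Alternative depth:** `< 20` reads supporting the alternative removes
  the variant. This reads the depth rule as alt-supporting reads (VCF AD
  alt field), the literal reading of "coverage for the alternative", not
  total site depth.
* **Rarity:** a variant is rare iff absent from the population
  allele-frequency table or strictly below 0.001.
* **Normalization:** per region,
  `n / (reads_mapped × read_size)`; per chromosome for rare variants,
  `n / (reads_mapped × read_size / chrom_length)`. Values are stored on
  the natural scale; log10 is applied only at reporting/plotting. The
  read size default is 98, the cDNA read length of the study's 26+98
  paired-end configuration.

`cohort_rank_test()` compares per-sample burden between cohorts,
one-sided by default under the hypothesis that burden is greater in the
case group. With 2 vs 4 samples the statistic is so discrete that the
choice of approximation is visible: at complete separation the
continuity-corrected normal approximation gives 0.0526 (printed as 0.053)
while exact enumeration of all 15 assignments gives 1/15 ≈ 0.0667. The
function always reports both, plus group means and standard deviations;
tests confirm the two converge (within 0.01 by 8 vs 8). When every value
is identical the variance is zero; p is reported as 1 with a degenerate
flag instead of NaN.

## The synthetic-data generator

The generator emulates the study conditions: 2 case and 4 control
samples; sparse, protamine-dominated expression; a mitochondrial gene
subset; cell-barcoded single-end 98-bp alignments on a ~90 kb synthetic
reference of three chromosomes; a region annotation partitioning every
base into exonic/intronic/intergenic with multi-exon CDS (non-trivial
frames, alternating strands); and a gnomAD-style allele-frequency table
straddling the 0.001 cutoff.

Expression is zero-inflated negative binomial: per-cell expected depth is
log-normal (median ≈ 60 UMI, so many cells sit below the 25-UMI floor,
as in real sperm data), gene means are `depth × weight` with a power-law
weight profile whose top two genes (the protamine analogues) carry well
over half the mass, NB dispersion 2, and 20% dropout applied uniformly.
About 6% of cells have their mitochondrial mass inflated past the 40%
threshold, emulating degraded cells. These distributional parameters are
free choices — the study reports no quantitative expression model and the
deposited data are controlled-access — chosen once to look like sperm
sequencing at desk scale; they are not calibrated to the real data.
Planted differentially expressed genes multiply the gene mean in case
cells by `exp(±LFC)`, so the cohort mean ratio equals the planted fold
change exactly in expectation, which is what the recovery tests check.

Alignments: each cell draws reads from a set of 500-bp expressed segments
(transcript analogues) plus one anchored read per planted site, so every
cell covers every planted variant — making truth-table recovery exact
rather than probabilistic. Carriers are drawn per cell with the planted
carrier fraction (realized counts are binomial, asserted against the 99%
binomial interval); carrier reads show the alternative with probability
`1 − e`, non-carriers with `e/3`, implemented by planting the allele and
then applying a uniform per-base substitution error to every base. Base
qualities are constant Phred 37. Reads per cell follow a negative
binomial (default mean 150, size 5) so some cells fall below and some
above the 100-read floor; tests that need exact recovery use a fixed
per-cell read count instead.

What the generator does **not** emulate: UMI collisions, doublets,
ambient RNA, splicing (reads are single-block), indels, fragment-length
variation, batch effects between samples, or the true genomic scale.
Passing tests therefore demonstrate the correctness of the *procedures* —
thresholds, statistics, recovery logic — not the error characteristics of
real sperm libraries.

All randomness flows from explicit seeds (the design seed plus fixed
stage offsets); no function touches the global random state, and
identical seeds reproduce outputs byte for byte, including the pipeline's
summary JSON.

## Problem sizes and calibration design

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which each property is statistically meaningful:
QC and DEG cohorts of 6 × 1500–2000 barcodes × 300–2000 genes;
variant-calling experiments of 300 cells × 150 reads; burden comparisons
at the study's 2-vs-4 sample shape.

The null calibration of the DEG test deserves a note. Under the sperm-like
sparsity profile a single 2-vs-4 cohort yields only a few hundred testable
genes, so the observed fraction of raw p < 0.05 has a binomial standard
error wider than the ±0.01 window we want to resolve. The calibration test
therefore pools six replicate null cohorts (~2000 tested genes), a
resolution choice that leaves the target and tolerance untouched. The
Bonferroni check is asserted as exact zero on a single study-shaped null
experiment and at family-wise scale across the pooled replicates — with
family-wise error ≤ 0.05 per experiment, the expected number of null
rejections across six experiments is ~0.3, and demanding a strict zero
over the pool would fail a perfectly calibrated procedure about a quarter
of the time.

## Limitations

* The per-cell caller assumes single-block alignments and ignores indels
  and phasing; spliced reads must be pre-split upstream.
* Pooling samples without batch correction is adequate for the synthetic
  data's design but real multi-donor experiments may need the alignment
  machinery this package deliberately omits.
* The cell-level rank-sum test treats cells as independent replicates;
  donor-level confounding is visible only through the reported per-sample
  structure.
* Quality thresholds are caller-relative: the 20-quality floor filters
  this model's binomial-tail score, and equivalence to other callers'
  QUAL at the same number is not claimed.
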