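---
title: "Methods: how srnapipe calls small RNAs, novel miRNAs and their targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how srnapipe calls small RNAs, novel miRNAs and their targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, rules and numerical choices behind each
stage of the pipeline, the parameters a user may want to turn, and what the
synthetic-data tests do and do not demonstrate about real libraries.

## Representations and conventions

Reads and references are held internally in the RNA alphabet (T is
normalized to U on input, `normalize_rna()`); genomes stay in DNA form
inside `Biostrings::DNAStringSet` objects and are converted at comparison
boundaries. All intervals are 1-based and closed, the native convention of
both GFF3 and the IRanges/GenomicRanges stack; keeping a single convention
end to end removes an entire class of off-by-one conversions that a 0-based
internal representation would require at every file boundary.

A library is a collapsed count table (`ReadLibrary`): unique sequence,
length, count, plus the label and totals. Reads outside the analysis range
are dropped at collapsing time. The default range is 18–30 nt; a `"gel"`
preset (16–30 nt) mirrors the wider gel-purification window some protocols
use. Counts are per library; cross-library statements (specificity, fold
differences) are made by joining two libraries' result tables.

## Annotation classification

Each unique read is assigned to exactly one category by precedence:

known mature miRNA > known star > rRNA > tRNA > snRNA > snoRNA > siRNA >
exon > intron > other.

Identity classes come first because a perfect match to a defined molecule
is more specific than positional overlap with a gene model. Known
mature/star matching is exact and full length — substring matching would
silently absorb isomiRs — while the structural-RNA classes match by
substring-or-equality on either strand of the reference, because the reads
in those categories are degradation fragments of much longer molecules.
Exon/intron assignment requires a genomic mapping hit overlapping the
feature by at least 1 nt, strand-blind (the strand of origin of a
degradation product is not knowable from the read). The resulting summary
is a partition: category rows sum exactly to the library totals, which the
tests assert on every fixture.

## Conserved miRNA quantification

A known miRNA is "present" iff some read equals its mature sequence
exactly; the count is that read's count. RPM uses the library's total
clean reads as denominator (count / total × 10⁶) — the standard
definition. Star abundance takes the star sequence from the reference
when available, otherwise derives it from the folded precursor with the
same duplex geometry used in discovery, and flags loci where the star
out-accumulates the mature.

## Novel miRNA discovery

The chain is: map → cluster → window → fold → excise → repeat filter →
MFEI filter → mature call → star call → context → families.

* **Mapping** (`map_reads`) reports *all* occurrences of each read on both
  strands with at most `max_mismatch` substitutions (default 1, no
  indels).
* **Clustering** (`cluster_hits`) merges hits on one chromosome/strand
  whose intervals are within `merge_gap` (default 200 nt — larger than any
  plausible precursor arm spacing, small enough to keep neighbouring loci
  separate).
* **Window extraction** pads the cluster span by `window_pad` (150 nt,
  retry at 75 nt), capped at `window_cap` (400 nt), reflecting plant
  precursor lengths from ~60 nt to beyond 350 nt.
* **Precursor excision.** The padded window is folded (RNAfold, MFE
  structure) and decomposed into stem-loop units — helix chains around a
  single hairpin loop, terminated at multiloop branch points and at
  interior loops wider than 8 unpaired bases on either side (helices
  separated by larger gaps are distinct structural elements, not one
  precursor stem). Within the selected unit the candidate is trimmed to
  the innermost base pair that still encloses the mature-eligible reads,
  then extended by `excise_margin` (5 nt) of flanking residues, and
  refolded. Computing MFEI on an excised candidate rather than on the raw
  window is essential: the index divides |MFE| by sequence length, so a
  genuine ~60-nt hairpin diluted in a 300–400 nt window of unstructured
  flank would never reach the 0.85 threshold. Excision is also what the
  established precursor-evaluation tools do before scoring.
* **Filters.** The repeat filter rejects windows containing a supplied
  repeat-library sequence, a tandem of ≥ 9 units with period ≤ 6, or
  dinucleotide entropy below 3 bits (random sequence sits near 4). The
  MFEI filter is strict: candidates must exceed 0.85, and a candidate at
  exactly 0.85 is rejected. The mature must be 20–22 nt, have at least 5
  reads in the discovering library (per-locus, per-library counts), and
  lie wholly on one arm without touching the terminal loop. Ties between
  equally abundant eligible reads break to the lexicographically smallest
  sequence, which keeps discovery deterministic.
* **Star calling** uses canonical Dicer geometry — both strands of the
  miRNA:miRNA\* duplex carry 2-nt 3′ overhangs — so the star runs from the
  partner of mature position L−2 to the partner of mature position 1 plus
  two nucleotides, skipping unpaired anchor positions inward along the
  pairing map. No star is derivable when more than half of the mature's
  positions are unpaired.
* **Context** is Intron/Exon when the precursor lies wholly inside one
  such feature, Overlap when it straddles an exon/intron boundary within a
  gene, Intergenic when it overlaps no gene. A precursor straddling a gene
  edge is reported Intergenic with a logged message; it is partly outside
  any gene model and the classical three-way scheme has no category for
  it.
* **Families** are single-linkage clusters linking matures of equal length
  at Hamming distance ≤ 1; family ids are ordered by each family's
  lexicographically smallest member, making the grouping
  permutation-invariant and idempotent.

Before discovery the pipeline strips reads classified as known
miRNA/star, structural RNA or exonic (transcript) matches, keeping
intronic and unannotated reads — intronic precursors are a substantial
fraction of genuine novel loci.

## Target prediction

The site model is gapless and antiparallel: a binding site has the
miRNA's length, and miRNA position *i* (1 = 5′ end, the plant-miRNA
convention that makes "positions 10/11" the cleavage site) faces site
position L−i+1. G:U wobbles are tracked but count as mismatches for every
positional rule — the conservative reading — while hybridization energies
(RNAduplex) still credit them with wobble stacking. Basic criteria:
≤ 3 mismatches, positions 10 and 11 clean, no run of more than 2
mismatches within positions 2–12, and MFE ratio (site energy over
perfect-complement energy) strictly above 0.75; the ratio is clamped to 0
for non-hybridizing sites, and the perfect complement is the denominator
convention. The strict subset requires zero mismatches in 2–12 and no two
adjacent mismatches anywhere. The scanner screens the positional rules
vectorially over all windows and computes duplex energies only for
surviving windows; tests verify exact agreement with an exhaustive
per-window evaluator.

## Conservation scan

Near-matches (≤ 4 substitutions, both strands) seed two asymmetric
windows, −50/+250 and −250/+50 relative to the match boundaries
(mirrored for minus-strand hits), covering both possible arm placements
of the mature on its precursor. Windows are screened with a local
alignment of the window against its own reverse complement (match +3,
mismatch −3, gap open −12, gap extend −2). Alignments are reduced to
non-crossing arm pairs (palindromic self-alignments cross their own
centre and are deduplicated via the position map), and an inverted repeat
is reported at arm length ≥ 15, identity ≥ 0.7 and arm score ≥ 50 — the
score threshold plays the role of einverted's default minimum score and
is what keeps random 300-nt windows clean. A hit is conserved when an
IR-bearing window, after precursor excision around the match, folds into
a single stem-loop with MFEI > 0.85 and the matched mature wholly on one
arm.

## The synthetic study generator

`scenario()` defaults describe the conditions the pipeline targets: a
200-kb genome, 24 three-exon gene models, 30 planted hairpins distributed
over Intergenic/Intron/Overlap contexts at roughly 57/37/6% (the
proportions reported for novel plant miRNA precursors), mature abundances
log-uniform on 5–500 so that discovery operates right at the 5-read rule,
star reads sampled at 5% of the mature count (miRNA\* strands are
degraded and rare), a degradation background biased to 24 nt for
seed-like libraries (21 nt for leaf-like), and substitution errors at
0.005 per base. Planted precursors are perfect stems of
mature + 5-nt extension with an unstructured A/C loop, two designed
non-pairing positions on the star arm (real stems are imperfect, and a
perfect inverted repeat would make every mature read also map antisense)
and a 2-nt 3′ tail, so the star sequence is known by construction.

What passing these tests shows: the operational rules are implemented
exactly, recovery at the stated abundances/error rates is high, and the
filters admit no false loci from random background. What they do not
show: behavior on real repeat landscapes (maize is transposon-rich; the
built-in repeat filter is a stand-in for a genuine repeat library), on
bulged/multiloop precursors beyond the 8-nt interior-loop tolerance, on
isomiR-dominated loci, or at sequencing depths where the 5-read rule
interacts with error correction.

Sizes used in the test suite — a 60-kb/8-hairpin fixture for module
tests, five 200-kb/30-hairpin studies for recovery, 50 transcripts of
500 nt for the scanner-oracle comparison — were chosen as the smallest
problems that still exercise every rule at realistic densities.

## Degenerate inputs and numerical notes

Empty libraries are an error for distribution/summary operations (the
fractions are undefined) and legal everywhere else; unmapped reads and
clusters with no eligible mature simply produce no output. Folding is
delegated to ViennaRNA's MFE engine; all energy-dependent expectations in
the tests are frozen fixtures produced once with this engine, since exact
energies differ between engines and versions. MFEI is reported
non-negative; gc_fraction = 0 is a domain error. RNG use is confined to
the generator and seeded per scenario; two runs of any stage on identical
inputs are byte-identical, which the suite asserts on whole report trees.

## Known limitations

Bowtie/blastn/einverted are replaced by exhaustive internal equivalents
that are exact but desk-scale; genome-scale inputs would need an indexed
mapper behind the same interfaces. The gapless site model cannot express
bulged target sites. Family grouping at Hamming ≤ 1 is a deliberately
simple proxy for miRNA family nomenclature. The published RPM figures of
the study this pipeline mirrors are not reproducible from its printed
totals under any per-million definition; `rpm()` implements the standard
definition and makes no attempt to match those two numbers.
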