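---
title: "Haplotype-resolved assembly-based SV calling with diplosv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-resolved assembly-based SV calling with diplosv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diplosv)
```

## The problem and the approach

Long-read assembly turns structural-variant calling into an alignment
problem: once each haplotype of a diploid genome is assembled into contigs,
an insertion or deletion shows up as a clean discrepancy between a contig
and the reference, rather than as a noisy pileup of individual reads.
`diplosv` implements the variant-calling half of such a pipeline. It
expects, as inputs, contig-to-reference and read-to-reference alignments
(BAM), the reference, and a phase-block table from an upstream
SNV-phaser; assembly and phasing themselves are out of scope and are
emulated by the package's fixture generator so that every stage can be
tested with exact ground truth.

The pipeline has four stages:

1. **Unphased-read partitioning.** Reads the upstream phaser could not
   attribute to a haplotype are assigned by unique k-mer fingerprints.
2. **Large-indel detection.** INS/DEL signatures are read off split contig
   alignments and large CIGAR operations, clustered within each haplotype,
   then paired across haplotypes into genotyped calls, filtered with read
   evidence, de-duplicated, and genotype-refined.
3. **Complex SVs.** Inversions and translocations come from strand- and
   chromosome-discordant split alignments and are filtered with read
   orientation/spanning evidence; duplications are recovered from insertion
   calls whose alternate sequence re-aligns next to its own breakpoint.
4. **Small indels.** 2–49 bp indels are collected from contig CIGARs and
   filtered by comparing the k-mer content of their contig context against
   the overlapping reads.

## Read partitioning by fingerprint k-mers

Each haplotype of a phase block (a *PS_HP*) gets a **raw k-mer set**: the
union of k-mers (k = 12, stride 1) of the phased reads whose alignments
overlap the block. The **fingerprint** of a PS_HP keeps the k-mers unique
to it among the candidate PS_HPs of a read (one overlapping block gives two
candidates, a read in or near a block junction gives four). A read is
scored by the intersection sizes `Sim_i` of its own k-mer set with each
fingerprint, normalised to `NormSim_i = Sim_i / sum(Sim)`, and assigned to
the best candidate when that score clears an empirical significance cutoff
— the (1 − r) quantile (r = 0.1) of the pooled null distribution of
normalised similarities. Reads with no significant candidate are assigned
to both haplotypes of their nearest block.

Four design choices in this stage deserve explanation, all driven by
failure modes we could reproduce at will on fixtures:

* **Membership by overlap, not majority.** If a phased read contributes
  its k-mers only to the single block with the largest overlap, a position
  near a block boundary can end up covered, in one haplotype's raw set, by
  no read at all — and its perfectly ordinary genomic k-mers then
  masquerade as "unique" to the other haplotype, producing confident wrong
  assignments. Letting each read contribute to every candidate block it
  overlaps removes this failure.
* **Read-support gating.** A k-mer enters a fingerprint only when seen in
  at least two distinct reads of its PS_HP. Sequencing-error k-mers are
  read singletons, so at realistic error rates the fingerprints would
  otherwise be dominated by error noise. Crucially, *exclusion* still uses
  the unfiltered sets: one stray observation of a k-mer elsewhere
  disqualifies it, otherwise the support filter itself recreates the
  coverage-gap pathology one level up.
* **Per-haplotype uniqueness for four-candidate groups.** A junction k-mer
  seen by one haplotype in both adjacent blocks is genuinely
  haplotype-discriminative; demanding uniqueness among all four sets would
  delete it from both fingerprints and blind exactly the boundary-spanning
  reads the two-block rule exists for. Uniqueness is therefore evaluated
  between the per-haplotype unions; as a consequence the two blocks of one
  haplotype may share junction k-mers, and a tie of the maximum score
  between them is resolved to the larger-overlap block (a tie *across*
  haplotypes still falls back to both-haplotypes).
* **The null.** The cutoff is estimated from the pooled non-maximum
  normalised similarities over all reads — the chance associations of
  diploid reads — with every value attaining a read's maximum excluded, so
  that same-haplotype ties cannot drag the cutoff up to the signal itself.

On fixtures with one heterozygous SNP per ~1.5 kb (a realistic human
density), 25% of reads with hidden provenance and 15× coverage per
haplotype, this recovers the true PS_HP for essentially all informative
reads at 0% error, ~98% at 2% error, and degrades monotonically (to ~50%)
at 10% error; reads overlapping no heterozygous variant are by construction
unassignable and take the both-haplotypes fallback.

## Large-indel signatures and clustering

For two segments of one contig, adjacent along the contig and consistent in
strand and chromosome, let `Contig_s/Contig_e` and `Ref_s/Ref_e` denote
query and reference coordinates (0-based half-open; minus-strand query
coordinates are flipped into the orientation in which query and reference
advance together). Two quantities decide everything:

* `Diff_dis = (Contig_2s − Contig_1e) − (Ref_2s − Ref_1e)` — the length
  difference between the contig and the reference across the junction,
  which approximates the SV length;
* `Diff_olp` — the overlap of the two alignments, on the reference for a
  candidate insertion (`Ref_1e − Ref_2s`) and on the contig for a deletion
  (`Contig_1e − Contig_2s`). A large overlap indicates an alignment
  artifact, not a variant.

An insertion is emitted when `Diff_dis ≥ 30` and `Diff_olp < 3000`, at
position `floor((Ref_1e + Ref_2s)/2)` with length
`|Contig_2s − Contig_1e + Diff_olp|` and the inserted contig substring as
its sequence; a deletion when `Diff_dis ≤ −30` and `Diff_olp < 3000`,
spanning `[Ref_1e, Ref_1e + |Diff_dis|)`. Large I/D CIGAR operations
(≥ 50 bp) are pooled with split-derived signatures — modern aligners
freely trade one representation for the other, and the clustering stage
absorbs the redundancy.

Within one haplotype, signatures are sorted by breakpoint and chained:
an edge joins adjacent signatures when the breakpoint shift is < 100 bp and
the size ratio (min/max) exceeds 0.5 — deletions additionally need
reciprocal overlap > 0.5 — and each connected component is represented by
its longest member. Pairing across haplotypes repeats the chaining at a
relaxed 200 bp shift cap on the merged per-block list; a component with
members from both haplotypes becomes `1|1`, otherwise the phase of the
contributing haplotype is kept.

## Filtering, redundancy removal, genotype refinement

* **Read support (50–250 bp calls only).** A call needs one same-type read
  signature within ±500 bp whose size ratio exceeds 0.5. Above 250 bp,
  read alignments are no longer the more reliable witness and the filter
  does not apply.
* **Deletion depth band.** For each candidate DEL, `sig_depth` is the
  summed length of DEL read signatures within ±1 kb divided by the
  candidate length; pooling these over candidates gives a vector whose
  median anchors an inclusive acceptance band `[lb·median, rb·median]`
  with per-technology ratios (hifi 0.2/2.6, clr 0.19/3.0, ont 0.24/2.8).
* **One-to-K redundancy removal.** Unlike chaining, *every* pair of
  same-type calls within a 500 bp neighbourhood is compared (shift caps
  500 bp INS / 300 bp DEL; size-ratio floors 0.5 INS / 0.1 DEL; sequence
  similarity `1 − editdist/max(len)` > 0.5), so a dissimilar false call
  sitting between two copies of the same variant no longer breaks the
  chain. The longest call of each component survives; the operation is
  idempotent.
* **Genotype refinement.** A 24-leaf decision tree over contig genotype
  (het/hom), size bin (≤/> 1 kb), SV type and technology thresholds the
  relative support ratio (supporting read signatures / local read depth
  over ±500 bp). The shipped thresholds come from a read-spanning model:
  only reads spanning the event with adequate anchors (~2 kb in total, for
  a ~12 kb read) support it, so a homozygote's expected ratio is the
  spanning fraction — near 1 for deletions of any size, but
  `(L_read − svlen − A)/L_read` for insertions — and each leaf sits at the
  midpoint of the het and hom expectations for its stratum. For insertions
  near or above the read length no read can span at all, support carries no
  genotype information, and the corresponding contig-homozygous leaf is 0:
  refinement never overrides the assembly there. Thresholds were
  calibrated on fixtures against a genotype-recovery target of ≥ 0.95.

## Complex SVs and small indels

Adjacent opposite-strand segments give an inversion over the
minority-strand segment's reference span. Aligners sometimes leave an
inverted contig segment entirely unaligned instead of reporting a
reverse-strand record, so an adjacent same-strand pair bracketing
similar-sized unaligned gaps on both the contig and the reference is
additionally probed by comparing the contig piece against the
reverse-complemented reference gap (≥ 80% identity emits an inversion over
the gap). An inversion is kept only if some read whose alignment touches a
breakpoint window aligns to the chromosome in two distinct orientations —
judged over all of the read's alignments, because the inverted piece of a
junction-crossing read maps near the *other* breakpoint. Adjacent
cross-chromosome segments give a translocation junction, kept when the
reads spanning both ±1 kb breakend windows reach a quarter of the local
depth; junctions are canonicalised (smaller breakend first) before merging
because a reciprocal exchange is seen from both derived chromosomes.
Duplications mostly surface as insertion calls, so every INS alternate
sequence is re-aligned within `max(1 kb, 2×svlen)` of its breakpoint using
a banded edit-distance scan (≤ 20% edits; the band halves adaptively when
it exceeds the matcher's internal limit); a proximal hit reclassifies the
call as a DUP over the matched interval, and the operation partitions its
input — no call is created or lost.

Small indels (2–49 bp) are collected from contig CIGARs as left-anchored
VCF-style records with their contig context (the inserted allele plus
20 bp flanks; deletions, whose bases are absent from the contig, carry the
40 bp junction context). An indel is kept only when strictly more than 70%
of its context k-mers occur in the reads overlapping the 100 bp window
around the anchor — contig-only artifacts fail this test while read-backed
indels pass it saturated. Externally phased SNPs pass through unmodified.

## The fixture generator

`generate_diploid_genome()` implants SNPs and SVs into a random reference:
heterozygous variants on one haplotype, homozygous on both, placed by
rejection sampling with a 1 kb isolation gap for SVs (150 bp for SNPs) and
kept clear of phase-block boundaries, so per-variant assertions never
interact. Translocations are reciprocal terminal-segment exchanges between
chromosome pairs. `fixture_contigs()` cuts each haplotype at the
haplotype-mapped block boundaries (one error-free contig per block per
haplotype, named `PS<block>_hp<h>_<n>`); `inject_contig_artifacts()` adds
assembly-error indels to contigs only. `simulate_reads()` draws reads to a
per-haplotype target coverage with truncated-normal lengths and
per-technology substitution/insertion/deletion error rates; read starts may
overhang chromosome ends (and are clipped) so coverage stays uniform to the
terminal bases, as in real sequencing; a configurable fraction (default
25%, the typical unphased remainder of an upstream phaser) hides its
provenance to exercise the partitioner.

What the fixtures deliberately do **not** model: repeat structure and
segmental duplications (variants are placed in effectively unique
sequence), technology-specific error profiles (homopolymer bias,
chimeras), assembly fragmentation beyond block boundaries, and
reference-bias effects. Passing tests on these fixtures therefore
demonstrate the correctness of the decision rules and the plumbing — not
calling performance in repetitive regions of real genomes.

## Problem sizes and numerical choices

The shipped benchmarks use a 1 Mb single-chromosome fixture with 40
INS/DEL of 50 bp–10 kb at 30× total (15× per haplotype) ~1% error reads for
end-to-end recovery; a 200 kb fixture at one het SNP per ~1.5 kb for the
partitioner; a 600 kb ten-chromosome fixture for the complex-SV stage; and
a 150 kb fixture for small indels. These sizes keep every stage's
behaviour measurable with exact truth while each run stays in the minutes
range. Alignment is delegated to minimap2 (presets `asm5` for contigs and
`map-hifi`/`map-pb`/`map-ont` for reads) through a single-threaded wrapper
so outputs are byte-deterministic; all internal coordinates are 0-based
half-open, converted to 1-based only when writing VCF; quantiles are
linear-interpolation empirical quantiles; ties in representative selection
go to the longest, then leftmost, call.

## Worked example

```{r example, eval = FALSE}
library(diplosv)

res <- run_all("diplosv_demo", ref_length = 1e6,
               spec = variant_spec(c("INS", "DEL", "SNP"), c(20, 20, 200), 50, 10000),
               coverage = 15, tech = "hifi", seed = 7)
glance(res$eval)     # recall, precision, F1, genotype concordance
tidy(res$callset)    # the final calls
autoplot(res$eval)   # breakpoint-shift distribution of true positives
```

## Known limitations

* The partitioner's fingerprints use k = 12 globally; for blocks much
  larger than a few hundred kilobases the k-mer space begins to saturate
  and a larger k (configurable) is advisable.
* The genotype decision tree's 24 thresholds are model-derived and
  fixture-calibrated; on real data with very different read-length
  distributions they should be re-examined (they scale with the spanning
  fraction, which depends on read length).
* The evaluator implements Truvari-style predicates with greedy
  closest-first matching; it is intended for fixture benchmarking, not as
  a replacement for external benchmarking tools.
* Interspersed duplications whose insertion site is far from the source
  locus are reported as insertions: the recovery procedure searches only
  the proximal window.
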