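---
title: "Comparing two cultivar genomes: methods and design notes"
author: "genopair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing two cultivar genomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genopair)
```

## What this package computes

`genopair` compares two closely related genome assemblies — think two
cultivars of the same crop, whose genomes are ~95% mutually syntenic — and
reports the classes of variation that differ between them:

* **one-to-one syntenic blocks**: base-level pairwise alignments filtered so
  that no block overlaps another on either genome (rearrangements allowed),
  and a stricter **colinear** set allowing no rearrangements at all;
* **presence/absence variation (PAV)**: segments of one genome (> 500 bp)
  that cannot be mapped to the other, with cluster calling, PAV-gene
  assignment, and hypergeometric pathway enrichment;
* **SNPs and short indels** (1–100 bp) read off the one-to-one blocks, with
  per-50-kb densities and **SNP-enrichment regions**;
* **inversions and translocations** classified from the disagreement between
  the one-to-one and colinear block sets;
* **k-mer genome-size estimation** and assembly N50/N90 statistics;
* **orthogroup duplication statistics** for a two-species membership table;
* **coding-sequence and protein consequence calling** (e.g. a serine-to-
  asparagine substitution in a herbicide-target enzyme) and in-silico PCR.

A first-class simulator (`run_simulate()`) generates cultivar pairs with
known truth for every one of these signals, which is how the package tests
itself end to end.

## The aligner

Real studies of this kind run external aligners (nucmer for whole-genome
blocks, BWA for window mapping). `genopair` ships a self-contained
equivalent so that every downstream rule is testable without external
binaries; externally produced alignments can be injected through
`read_paf()` instead.

1. **Seeding.** Anchors are maximal exact matches (MEMs) of length at least
   `min_mem_len` (default 20 bp), on both strands. They are found by joining
   exact k-mer positions (k = `min_mem_len`, 2-bit encoded) of the two
   genomes and collapsing runs of consecutive hits on a diagonal; a shared
   substring of length L contributes exactly its L − k + 1 constituent
   k-mers, so every collapsed run is maximal on both sides by construction.
   `N` never matches and breaks anchors — conservative in assembly gaps.
2. **Chaining.** Co-strand anchors are chained by dynamic programming into
   collinear chains: strictly increasing on both axes (the query axis
   reversed for `-` chains), inter-anchor gaps at most `max_anchor_gap`
   (default 1,000 bp) on both axes. The chain score is the summed anchor
   length minus once-counted overlaps between consecutive anchors. Because a
   valid predecessor must lie within the gap bound on the reference axis,
   restricting the DP look-back window to that bound is exact, not an
   approximation.
3. **Gap closing.** Inter-anchor gaps are closed by banded global alignment
   with unit scores (match +1, mismatch −1, gap −1) and a deterministic
   tie-break: diagonal, then reference-consuming gap, then query-consuming
   gap. Equal-length gaps at Hamming distance ≤ 1 are provably all-column
   alignments and skip the DP. A gap whose length difference exceeds the
   band (default 100 bp) is retried with a doubled band, then **splits the
   block** — this is what leaves PAV insertions and deletions unaligned.
   Blocks shorter than `min_block_len` (200 bp) are discarded.

### One-to-one and colinear filters

The one-to-one filter drops blocks under `min_identity` (90%, the published
identity cut) and then selects a maximum-total-score subset with no overlap
on either genome. Rather than scheduling the reference axis and then the
query axis greedily, the optimum is computed exactly per conflict-graph
component by branch and bound (components beyond 28 blocks — unseen in
practice — fall back to axis-wise interval scheduling). Block score is
`aligned_length × identity`.

Two engineering details matter here:

* **Overlap slop.** Seed extension can spill a few bases across an event
  junction (the first base of an insertion matches the next reference base
  with probability 1/4), so neighbouring blocks genuinely overlap by 1–20
  bp. Treating those as hard conflicts would discard whole multi-kilobase
  blocks. Overlaps of at most `overlap_slop` (50 bp) are therefore not
  conflicts; after selection they are trimmed from the lower-scoring block,
  walking its edit runs, so the output still never contains two blocks
  overlapping on either genome.
* **Colinear as a subset.** The colinear ("global, no rearrangements") set
  is the maximum-score chain of `+`-strand blocks strictly increasing in
  both genomes, chosen per reference chromosome *within* the one-to-one
  output. Running the two filters independently could let a high-scoring
  inverted block displace a colinear one from the one-to-one optimum, in
  which case neither set would contain it and the subset relation (which
  the rearrangement classifier relies on) would break. The candidate set
  for structural variation — one-to-one minus colinear — is unchanged by
  this choice.

### Window mapping and PAV

PAV calling tiles the query genome into 500-bp windows stepped by 100 bp
(with a final window anchored at the chromosome end so every base is
windowed), maps each window against the other genome, and flags windows
that are unmapped or covered below 20% (strict, matching the published
wording "less than 20%"). Coverage is the fraction of window bases covered
by the best single placement — anchors clustered per target chromosome,
strand and diagonal, with internal gaps up to 500 bp (the window mapper's
gap allowance) — and the denominator is the full window length. Flagged
windows are unioned into segments; segments not strictly longer than 500 bp
are discarded ("larger than 500 bp" read strictly; the threshold is a
parameter).

The merged-window segment localizes a PAV breakpoint only to within one
step (100 bp). Each segment is therefore refined to the longest per-base
seed-coverage gap it contains, which lands within ~10 bp of the true
junction; the refinement never moves a boundary by more than one step from
the window-grid call.

Clusters chain segments across gaps ≤ 100 kb (single linkage) and are kept
when segments cover more than 10% of the chained span. PAV genes are
transcripts with more than 75% of their CDS bases covered by segments,
computed on interval unions. Pathway enrichment is the upper-tail
hypergeometric probability with Benjamini–Hochberg adjustment across terms
(the adjustment is this package's choice; the underlying study names only
the raw test).

## Variants and enrichment regions

SNPs are mismatch columns and indels are gap runs of the one-to-one blocks,
with positions in both genomes (1-based in the VCF-like output; query
positions on the forward strand). Columns containing `N` are excluded.
Adjacent single-base indels of the same kind — consecutive on the genome
carrying the bases, anchored at the same position of the other genome —
merge into one record, reproducing the published merging rule.

SNP density uses non-overlapping 50-kb windows (the published figure states
the window size without a step, so tiles rather than sliding windows); the
last partial window keeps its true span. The enrichment threshold is
1.5 × the mean count over full windows — computed exactly, with a
`threshold_override` to reproduce a published rounded cut such as "≥ 180
per 50 kb" — and partial windows are flagged against a span-prorated
threshold. Flagged windows merge across gaps ≤ 100 kb; a report-layer
filter for spans > 450 kb is available but off by default. Genome-wide
per-kb densities take their denominator as an explicit argument because
published densities are ambiguous about theirs.

## Rearrangement classification

Candidates are one-to-one blocks absent from the colinear set. A `-` block
is an inversion. A `+` block is compared with its nearest flanking colinear
blocks on the reference: a different query chromosome than the flanks'
consensus makes it an inter-chromosomal translocation; the consensus
chromosome but broken query order makes it intra-chromosomal. A `+`
same-chromosome candidate still in order (a scoring casualty, not a
rearrangement) is dropped. Adjacent same-type candidates within
`max_anchor_gap` on both genomes merge into one event.

## K-mer genome size

Canonical 17-mers (lexicographic minimum of k-mer and reverse complement)
are counted from reads; the genome size is total k-mers above the error
cutoff divided by the peak depth. The cutoff defaults to the histogram's
first local minimum — the valley between the error peak near depth 1 and
the genomic peak. The peak is the modal depth refined to a count-weighted
centroid over 60–140% of the mode: the integer mode jitters by ±1 between
runs, which alone moves the estimate by several percent at 40×, while the
centroid is stable (observed recovery error ≤ ~1% on 200-kb simulations at
40× with 0.2% read error).

## The simulator and what it does (not) emulate

`derive_cultivar()` plants, in a fixed order — inter-chromosomal
translocations, intra-chromosomal translocations, inversions, PAV
deletions/insertions, short indels, SNPs — so that truth coordinates remain
single-pass liftable; every edit is logged with coordinates in both
genomes, and replaying the truth set on the ancestor reproduces the derived
genome byte for byte (tested across many seeds). Structural events are
placed without overlap and with safety margins; a single RNG stream per
seed is consumed in a documented order, so identical seeds give
byte-identical bundles.

Default conditions describe a closely related cultivar pair: background
SNP rate 0.002/bp with 20% of the genome in 200-kb enrichment blocks at
3× density (the underlying study found ~20% of windows enriched at its
1.5× cut); indel events at 4 × 10⁻⁴/bp with geometric lengths of mean
~4 bp truncated at 100 bp (matching ~0.39 indels and ~1.54 indel bp per kb);
PAV lengths a two-part mixture with 99% of mass between 501 bp and 5 kb
(uniform within each part); a few inversions of 5–50 kb and translocated
segments of 5–30 kb. GC content defaults to 0.46.

Two deliberate simplifications matter for interpreting test results:

* **No repeats.** Ancestor sequence is i.i.d. random, so 20-mers are
  essentially unique and mapping is unambiguous. Real plant genomes are
  ~half transposable elements; there, PAV calls inside repeats and anchor
  multi-mapping would degrade precision in ways these tests cannot reveal.
  The thresholds and filters are faithful; the measured recall/precision
  are upper bounds specific to repeat-free sequence.
* **Grid-aligned enrichment blocks.** Planted enrichment blocks start on
  the 50-kb analysis grid. A block straddling window boundaries has edge
  windows of mixed density that fall below the 1.5× threshold, so no
  50-kb-tiled method can flag them — with the worst offset, up to ~25% of
  a 200-kb block is unrecoverable by construction. Snapping the generator
  to the analysis resolution keeps the recovery property about the method,
  not about sub-resolution placement.

Reads are substitution-error only, uniform, without quality strings;
read-based analyses here need nothing more.

## Problem sizes and numerical choices

The end-to-end recovery analysis runs on a 2 × 1 Mb pair with 30 PAV
segments (0.6–8 kb), 3 inversions, 2 translocations and ~5,600 SNPs; it
completes in well under a minute and recovers PAV with 100% recall and
precision at ±100 bp, SNPs at ≥ 99% recall and precision, all structural
events, and every enrichment block. K-mer recovery uses a 200-kb genome at
40×. These sizes were chosen so the whole battery runs comfortably on a
laptop while every rule still has enough events to fail visibly if broken.

Degenerate inputs are defined rather than accidental: empty anchor sets
and empty truth sets produce empty, schema-complete outputs; a chromosome
shorter than a window is skipped with a warning; a transcript without CDS
is skipped with a warning; an empty length list or a histogram without a
genomic peak is an error. Ties are broken deterministically everywhere
(alignment traceback order; chain extraction by descending score, then
position).

## Known limitations

* Alignment ambiguity under unit scores: a SNP immediately adjacent to an
  indel can be absorbed into an equally scoring gap arrangement, so ~0.5%
  of SNPs at such junctions are represented differently from the planted
  edit. Affine gap scores would reduce this but are out of scope.
* The one-to-one filter's exact optimisation is per conflict component;
  pathological inputs with one giant component fall back to the axis-wise
  heuristic (with the subset-score guarantee only for the exact path).
* In-silico PCR is exact-match only — appropriate for primers designed
  against the assemblies being compared, not for degenerate primers.
* The rearrangement classifier reports block-resolution breakpoints; it
  does not refine them to base pair.
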