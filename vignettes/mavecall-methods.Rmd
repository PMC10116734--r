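---
title: "mavecall: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mavecall: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the choices
behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Coordinate conventions

Variant positions (`pos`) are 1-based transcript coordinates, as in VCF.
CDS bounds are 0-based half-open; BED and bedgraph output stay 0-based
half-open. All internal tables carry 1-based inclusive alignment spans
(`start`, `end`).

## The spike-in simulator

`plan_edits()` decides, for each requested variant, how many fragments to
edit: `round(target_frequency × fragment coverage)` with rounding half away
from zero and a floor of one fragment whenever the position is covered.
Fragment coverage counts proper pairs with at least one mate across the
position, before any deduplication — the simulator edits raw libraries, and
truth counts are fragment counts. Three eligibility rules constrain the
uniform, seeded, without-replacement sample:

1. at least one mate must cover **all** edited positions (a mate that
   partially covers an MNP is still edited on the covered prefix/suffix, so
   mates never disagree with the planned allele);
2. with `conversion_buffer` *b* > 0 (default 3 nt, matching the caller's
   MNP merge window), no pre-existing mismatch may lie within *b* nt of any
   edited position in either mate — this is what prohibits *variant
   conversion*, the merging of a spiked variant with an adjacent error into
   a spurious higher-order allele; `conversion_buffer = 0` disables the
   prohibition;
3. a fragment already claimed by any variant is ineligible, so requests at
   the same coordinate receive disjoint fragment sets and no read is edited
   twice.

If fewer eligible fragments exist than requested, the variant is reported
`unplaceable` with its achieved count — never silently truncated.
`apply_edits()` substitutes alternate bases at the planned read coordinates
with base qualities untouched; all other reads pass through byte-identical.

## Alignment

The package aligns reads with an internal, deterministic, gapless
seed-and-verify aligner: exact 15-mers at three read offsets propose
candidate placements on either strand, candidates are verified by
full-length mismatch counting, and the placement with the fewest mismatches
wins (ties: leftmost, then "+" strand; acceptance threshold 10% mismatches).
This is a deliberate design choice, not a shortcut: every library this
package simulates or edits contains substitutions only (InDel simulation
and calling are out of scope), so gapless end-to-end placement is exact,
reproducible, and free of gap-penalty tuning. The same decision makes the
validation round-trip sharp — recall losses cannot hide in aligner
heuristics. Users with gapped or clipped data can substitute any external
short-read aligner through `external_aligner()`'s command template and
import SAM/BAM via `read_alignments_sam()` (gapless records only enter the
internal model). Adapter and 3′-quality trimming is likewise a pass-through
by default, with an optional `fastp` delegation in `trim_reads()`; the
synthetic libraries carry no adapters.

## The caller

A pair is discarded outright if either mate's edit distance (`nm`,
mismatches against the reference as aligned) exceeds `max_nm`; the filter
applies to raw per-mate NM, with no discount for the bases of the candidate
variant itself — simpler, and consistent with using NM as a quality feature.
A mismatch is emitted only where **both** mates align across the position and
call the same non-reference A/C/G/T base with both qualities at or above
`min_bq` (and above zero: masked bases never participate; N calls never
participate). Positions covered by one mate only are uncallable — strict
concordance. The library designs the generator emulates have fully
overlapping mates, so this costs nothing there; on partially overlapping
designs the uncallable fraction is visible in the coverage track.

Phased mismatches of one pair merge greedily left to right while the total
reference span stays ≤ 3 nt (positions *i*, *j* merge iff *j − i* ≤ 2);
positions inside a merged span where the read matches the reference
contribute that (matching) base to both alleles. This yields exactly the
SNP / di-nt MNP / tri-nt MNP classes and no haplotype calls; when four or
more mismatches cluster, the leftmost-maximal greedy partition is the
defined behaviour and is tested against exhaustive enumeration.

Counts aggregate identical `(pos, ref, alt)` components once per fragment;
the frequency denominator is fragment coverage at the variant's leftmost
position, where coverage counts fragments with at least one unmasked base
across the position (mates of one fragment count once). Feature summaries
use the lower median (for even counts, the smaller middle value) —
determinism over convention.

## Primer masking and consensus deduplication

A mate's originating primers are determined per mate, independently of its
partner: (1) a same-strand primer whose aligned span, extended by a buffer
upstream of the primer 5′ end, contains the read 5′ end; (2) an
opposite-strand primer whose extended span contains the read 3′ end. The
buffer is 15 nt for amplicon designs and 3 nt for RACE-like designs (it
absorbs quality-trimmed ends and small alignment-start drift). Bases of a
read overlapping an originating primer's aligned span get base quality 0 —
the call and coverage layers then ignore them — while readthrough coverage
from adjacent tiles, whose read ends satisfy neither criterion, keeps its
qualities and is what makes variants under primers callable at all. Masking
never alters base calls and keeps pre-mask qualities, so it is lossless.

Deduplication groups pairs by (UMI, R1 leftmost aligned coordinate — not
template start) with the directional-adjacency rule: within a position
stratum, an edge runs from UMI *A* to UMI *B* when their Hamming distance is
1 and `count(A) ≥ 2·count(B) − 1`; components grow breadth-first from the
highest-count UMIs (canonical order: count descending, then lexicographic,
making grouping invariant to input order). The consensus takes, at each
aligned position, the majority base among covering duplicates; two-way ties
resolve by reference match, then higher supporting base quality, then a
seeded random choice. Duplicates not covering a position abstain. The
consensus base quality is the maximum among duplicates supporting the chosen
base — the evidence for the consensus base is at least as strong as its best
supporter; the mean would understate it after a majority vote. Deduplication,
when requested, directly follows alignment and precedes masking.

## The error model

Mate concordance eliminates independent single-read sequencer miscalls at
rate ≈ r²; the errors that survive it in real libraries are
molecule-level — polymerase errors during library preparation, present in
both reads of the pair. The generator therefore applies its six
strand-collapsed substitution-class rates (A>C/T>G, A>G/T>C, A>T/T>A,
C>A/G>T, C>G/G>C, C>T/G>A) at the fragment level, adds an independent
per-read miscall rate (`read_error_rate`, attenuated by the quality shift
`error_bq_shift`, default −12, that real miscalls show), and a separate
`primer_error_rate` confined to primer-derived segments so masking tests can
show those errors vanish. Base qualities follow a linear per-cycle decay
with Gaussian jitter. What passing tests on these libraries do **not** show:
real platform-specific error motifs (homopolymer context, optical
duplicates, index hopping), InDel errors, and quality-score binning are not
emulated, so classifier accuracies here bound behaviour on synthetic, not
real, data.

Balanced truth sets sample NNK-consistent single-codon variants (default
SNP proportion 0.25, remainder split evenly between di- and tri-nt MNPs;
the draw is constrained so the running component-mismatch total — SNP 1,
di 2, tri 3 — lands exactly on the negative control's false-positive
mismatch count) with frequencies resampled from a mutagenized library's
empirical distribution. Training examples come from simulating that truth
set into the NC alignments, re-calling at min count 1 with the NNK signature
flagged (not dropped — the signature must stay a feature), and labelling by
truth-set membership; calls outside the CDS or with frequency ≥ 0.3 are
excluded.

Features: log₁₀ frequency; variant type; signature match; substitution class
of the first changed base; upstream/downstream reference base; R1 and R2
median supporting base qualities; R2 median read position and edit distance
(R1's are collinear and omitted). RACE-like designs add the eight
per-sample-strand R1/R2 quality, R2 read-position and R2 edit-distance
medians plus the absolute strand count difference (19 features total);
strand-specific medians missing because one strand had no observations are
imputed with the feature median (rough fix). MNPs take the substitution
class of their first mismatched base.

Evaluation is nested 10-fold stratified cross-validation: inside each outer
fold, 20% of the training data tunes hyperparameters by 5-fold CV over a
small grid (random forest: mtry; gradient boosted trees via xgboost:
rounds × depth; elastic net: α × λ; SVC: cost; kNN: k plus greedy forward
selection of 3–10 features — a best-subset stand-in that keeps the same
protocol role), the model refits on the full fold and scores the held-out
fold. The final model refits on all data; random forests report
mean-decrease-in-accuracy importances. Scoring removes calls whose
predicted error probability strictly exceeds the cutoff (default 0.5;
filter-chain criterion 6 uses 0.49), and in replicate-aware mode only when
predicted an error in **all** replicates.

## Post-calling filter chain

Criteria run strictly in this order, each charged with the records it
removes: (1) inside the mutagenized target region; (2) NNK signature;
(3) single-codon change; (4) SNP count ≥ 2, MNP count ≥ 1; (5) RACE-like
strand count difference ≤ 64; (6) classifier-predicted error in all
replicates (cutoff 0.49); (7) observed in all replicates. The order is part
of the method: a record violating several criteria is counted against the
first. Background subtraction records
`log10(f_mut) − log10(f_nc)` per shared allele and flags alleles absent
from the negative control (adjustment 0). Downstream differential-abundance
statistics (wild-type normalisation, moderated tests, multiple-testing
correction) are intentionally out of scope; the chain ends at clean
per-replicate tables.

## Problem sizes and determinism

The validation round trip uses a 50-codon (150 nt) transcript with fully
overlapping 2×150 mates so every position has fragment coverage 10,000 and
each of the 187 variants sits at exactly 10/10,000 = 0.1%; the error-model
demonstration uses a 120-codon transcript, three 150-nt amplicon tiles and
4,000 fragments with class rates of 2×10⁻³ (C>A/G>T), 1.5×10⁻³ (C>T/G>A)
and 2×10⁻⁴ elsewhere — enough background error calls (hundreds) to train
on while keeping a desk-scale footprint. Every stochastic step (fragment
sampling, error injection, edit placement, fold assignment, tie-breaks)
derives its RNG stream from one user seed, so identical inputs and seed give
byte-identical outputs.

## Known limitations

Single transcript, single contig; no InDel simulation or calling; strict
mate concordance leaves single-mate regions uncallable; the internal aligner
requires reads to fit end-to-end within the reference; duplex UMIs and
barcode-haplotype designs are out of scope; the CLI is a thin convenience
wrapper, not a workflow manager.
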