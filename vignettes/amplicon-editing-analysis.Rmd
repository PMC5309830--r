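---
title: "Quantifying CRISPR-Cas9 editing outcomes from amplicon deep sequencing"
author: "indelScope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CRISPR-Cas9 editing outcomes from amplicon deep sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelScope)
```

## The problem

When Cas9 plus a single-guide RNA is delivered to a cell population, the
double-strand break at the protospacer is repaired predominantly by
non-homologous end joining, leaving a mosaic of insertions and deletions
(indels) centred on the cut site. Deep sequencing of a PCR amplicon spanning
the target — typically paired 2×300 nt reads that overlap across the whole
amplicon — is the standard way to quantify that mosaic: what fraction of
reads is edited, how large the indels are, where they fall, and, most
importantly for a knockout experiment, what fraction of alleles carries a
mutation expected to disrupt the protein (a frameshift, a premature stop, a
damaged splice donor). When the edited population is carried through serial
passages without clonal selection, the same analysis repeated per passage
answers whether the edited fraction is stable in culture.

`indelScope` implements this analysis end to end: FASTQ in, per-read
mutation calls and per-sample outcome fractions out, plus a seeded simulator
that generates read sets with a per-read truth manifest so that every stage
of the pipeline can be validated without access to external sequencing data.

## The coordinate system: the `Amplicon`

Everything is called against one reference amplicon holding a single coding
exon with its flanking introns. The annotation consists of five 1-based
closed intervals — `exon`, `intron5`, `intron3`, and two splice windows —
plus `frameOffset`, the codon phase of the exon's first base (needed because
an internal exon need not start on a codon boundary). The 5' splice window
must abut the exon on its 5' side and the 3' window on its 3' side; validity
checking rejects overlapping, out-of-bounds or non-abutting intervals at
construction time. In the toy system used throughout the tests the 5' window
carries the 12-nt donor motif `TTAAAAGCTTCC`.

Guides are located with `locateGuide()`, which scans both strands for the
20-nt protospacer immediately followed by the PAM (NGG by default, SpCas9).
The predicted blunt cut is placed between protospacer bases 17 and 18 —
3 bp from the PAM-proximal end, the canonical SpCas9 geometry. The paper
trail behind a given experiment usually reports only the protospacer
sequences, so localization is always re-derived from the reference; zero or
multiple matches are hard errors.

## Read preparation

*Trimming.* `trimReads()` removes the best 3' adapter match (at most 10%
mismatches over at least 3 aligned bases, "best" maximising matching bases)
and then applies the standard running-sum 3' quality trim: scanning from the
3' end, it accumulates `q − cutoff` and cuts at the leftmost minimum of the
partial sums when that minimum is negative. Defaults (`qualCutoff = 20`)
follow common practice for this class of data. Trimming never lengthens a
read, and quality trimming is idempotent.

*Merging.* `mergePairs()` reverse-complements the reverse mate and scores
every relative placement with at least `minOverlap = 10` overlapping bases,
choosing the placement with the smallest mismatch fraction (ties broken
toward the longer overlap, then the smaller offset — fully deterministic).
The pair merges when that fraction is at most `maxMismatchFrac = 0.25`;
disagreeing overlap bases take the higher-quality call, with the forward
base winning quality ties. Because amplicon reads are short, the exhaustive
scan is exact and needs no heuristics. Pairs that fail to merge are counted
in QC and excluded from mutation analysis: only contiguous reads that span
the regions of interest are classified.

## Alignment and event extraction

`alignReads()` performs optimal semi-global alignment under an affine gap
model: reference end gaps are free (reads are amplicon-contained by design),
the entire read must align, and a gap of length $L$ scores
$g_{open} + L \cdot g_{ext}$. The defaults
($+2/-4$ match/mismatch, $g_{open} = -12$, $g_{ext} = -1$) were chosen so
that a 50-bp deletion (the largest event the simulator plants, and the upper
end of what Cas9 NHEJ outcomes at a single cut typically produce) costs far
less than the equivalent run of mismatches, keeping large deletions
representable as single events. Semi-global rather than local alignment
guarantees internal deletions are never absorbed into soft-clips.

Three numerical choices make event calls reproducible:

* **Deterministic traceback** — at equal score the traceback prefers a
  match/mismatch column over a deletion over an insertion, and the endpoint
  with the smallest reference coordinate.
* **Left normalization** — an indel inside a repeat has many equivalent
  placements; every indel is shifted to its smallest reference coordinate
  (the VCF convention), so positional profiles and truth comparisons are
  convention-free.
* **Coalescing** — adjacent gap columns of the same kind become one indel
  event, and runs of mismatch columns become one substitution event (so a
  2-nt substitution inside a splice window counts as 2 changed
  nucleotides).

A read equal to an exact substring of the reference is recognised before
the dynamic program runs; an exact full-length match attains the maximal
possible score, so this fast path is provably optimal and returns the same
leftmost placement as the full traceback.

Alignments of queries longer than the reference plus a configurable
allowance (100 nt) are refused — such reads indicate mis-paired input, not
editing.

## The region filter

Only reads whose aligned span contains both the 5' splice window and the
whole exon enter mutation-frequency evaluation. Coverage is positional, not
literal: a read whose splice window is deleted still *covers* the window and
passes the filter. Requiring the literal motif would silently discard
exactly the reads whose splice-site disruption the analysis is meant to
count; the literal-motif variant remains available as
`passesRegionFilter(..., requireMotif = TRUE)` for comparison. The filter is
monotone: extending a read's span can never turn a pass into a fail.

## Per-read classification

For each filter-passing read:

* **Coding category.** Let $L$ be the sum of signed lengths of indel events
  overlapping the exon (insertions at exon-internal junctions count $+L$,
  deleted exonic nucleotides $-L$; an insertion exactly at an exon boundary
  belongs to the intron side). No events → `unmodified`; exon-overlapping
  indels with $L \not\equiv 0 \pmod 3$ → `frameshift`, otherwise
  `in_frame`; all events outside the exon → `noncoding`. The frame is
  decided on the *net* $L$ across all indels of the read, which is what
  determines the downstream reading frame. Substitution-only reads touching
  the exon keep the frame and are classified `in_frame`, judged by protein
  consequence, and — being SNVs — never count as disruptive.
* **Splice changes.** Per window, the number of reference nucleotides
  deleted or substituted inside it plus the nucleotides inserted at
  junctions strictly inside it.
* **Protein consequence.** The mutant sequence is reconstructed from the
  events and the exon boundaries lifted through them. If the net exonic
  indel length is a multiple of three, the mutant exon alone is translated
  in frame; if the frame is shifted, translation continues past the exon
  into the downstream reference until a stop codon or the sequence end.
  This pre-mRNA read-through is an approximation — the true downstream
  exons are outside the amplicon — and is how frameshift-induced stops are
  caught. `prematureStop` is set when this translation stops where the
  reference exon translation does not; `residueChanges` is the Levenshtein
  distance between the reference exon peptide and the mutant peptide
  truncated at its first stop, counting substituted, inserted and deleted
  residues uniformly. The paper trail behind such analyses rarely defines
  "residue changes" operationally; peptide edit distance is the uniform
  choice.
* **Disruptive call.** A read is potentially disruptive when its 5' splice
  window carries more than `spliceChangeMax = 1` changed nucleotides, or a
  coding indel causes a premature stop or more than `residueChangeMax = 5`
  residue changes. Explicitly excluded: substitution-only reads, 3' splice
  window changes, and in-frame indels affecting at most 5 residues. The two
  published phrasings of this rule (a threshold on residue changes, and an
  exclusion of small in-frame indels) are reconciled in the only consistent
  way: in-frame indels are excluded *only* when they affect ≤ 5 residues.
* **T7E1 detectability.** The T7 endonuclease I mismatch-cleavage assay
  only recognises indels of ≥ 2 nt; each read is flagged accordingly, which
  lets sequencing-based and enzymatic estimates be compared like for like.

## Per-sample summaries and denominators

`summarizeSample()` reports every fraction with its denominator attached,
because two different denominators are in play: the
frameshift / in-frame / noncoding split is computed over *modified* reads
only (unmodified reads are excluded from that panel), whereas the splice
and disruptive fractions are computed over all *filter-passing* reads. The
signed indel-size histogram gets a 0 bin counting reads with no indel, and
the positional profile counts, per reference position, reads with a
deletion or substitution covering it and insertions at that junction. With
a guide present, the fraction of indel events whose nearest edge lies
within `nearTargetWindow = 10` bp of the predicted cut is reported.

## Stability across passages

`comparePassages()` takes the disruptive counts of one lineage across
passages and reports per-passage Wilson 95% score intervals, all pairwise
pooled two-proportion z-tests, and one stability call. The pairwise
p-values are Holm-adjusted and the lineage is declared stable when no
adjusted p-value falls below `alpha = 0.05`. The adjustment is a deliberate
design choice: with three passages there are three correlated pairwise
tests, and declaring instability when *any* unadjusted test rejects would
inflate the family-wise false-alarm rate to roughly twice the nominal
level; Holm keeps the family-wise type-I error at `alpha` while remaining
more powerful than plain Bonferroni. Raw p-values are reported alongside
the adjusted ones.

## The simulator and what passing its tests does (and does not) show

`simulateReads()` emulates the study design the package targets: paired
2×300 nt reads covering a ~440 nt amplicon, a configurable edited fraction
(deterministically `round(n × f)` edited reads, shuffled — so small-`n`
tests are exact; a binomial mode exists for calibration work), one planted
indel per edited read, and uniform per-base substitution sequencing errors
(default $10^{-3}$). Indel sizes follow a geometric body (most indels a few
nt) with a 15% uniform tail up to 50 nt; positions centre on the predicted
cut with discretized normal jitter (sd 4 nt), placing ≥ 90% of events
within 10 bp of the cut. In the default toy amplicon the guide sits 3 nt
into the exon, so the cut falls ~19 nt from the 5' splice window and the
large-deletion tail clips the splice window in a few percent of edited
reads — the qualitative behaviour real editing data shows at this locus
geometry. An unedited control is `editedFraction = 0` with errors only.
Every read receives a truth-manifest row computed from the planted event by
the same closed-form classification rules, independently of the
read-processing path, plus exact sample-level fractions.

The simulator deliberately does **not** model: PCR chimeras, quality-score
error profiles (qualities are flat; errors are uniform substitutions),
indel sequencing errors, multi-event alleles, microhomology-biased repair
spectra, or the preferential dropout of large-deletion alleles during
amplification and quality filtering. Consequently, passing the recovery
tests shows that the *pipeline* is correct and calibrated under the stated
generative model — it does not certify accuracy on real data where those
unmodelled effects (especially large-deletion dropout, which biases the
disruptive fraction downward) are present. Estimates of
substitution-sensitive quantities (such as the overall modified fraction)
are only interpretable against the matched unedited control, which is
exactly why such controls are sequenced; the indel-derived fractions
(frameshift, disruptive, splice-disrupted) are robust to substitution
noise.

## Problem sizes and validation layout

The test suite validates each stage against independent oracles: a
row-vectorized slow affine-gap dynamic program for alignment scores (500
random pairs up to 60 nt), exhaustive classification of every single indel
of lengths 1–50 at every position of a 300-nt amplicon against the
closed-form rule, brute-force translate-and-compare for protein
consequences, and textbook closed forms for the proportion tests. End to
end, an error-free 2,000-read sample must be recovered *exactly*
(fractions and every planted event), a noisy 20,000-read sample within
three binomial standard deviations of its manifest truth, a 10,000-read
control must stay clean, and the stability call is calibrated on 200
null triplets of 5,000 reads per passage. These sizes keep the full
validation run comfortably on a laptop while leaving the binomial
tolerances tight enough to detect real biases; `scripts/acceptance.R`
recomputes the headline numbers from scratch at the same sizes.

## Known limitations

* Translation read-through after a frameshift uses intronic (pre-mRNA)
  sequence because downstream exons are outside the amplicon; stop
  positions beyond the exon are therefore approximate.
* The frame rule uses the net exonic indel length per read; a per-event
  alternative (any out-of-frame event → frameshift) is not currently
  exposed.
* One guide per analysis: samples edited with different guides are analysed
  as separate samples against the same amplicon.
* The aligner is a single-reference amplicon aligner, not a read mapper; it
  assumes every (merged) read originates from the amplicon.
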