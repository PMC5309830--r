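#' @include indelScope-package.R
NULL

.asIRange <- function(x, what) {
  if (is(x, "IRanges")) {
    if (length(x) != 1L) stop(what, " must be a single interval")
    return(x)
  }
  if (is.numeric(x) && length(x) == 2L)
    return(IRanges(start = as.integer(x[1]), end = as.integer(x[2])))
  stop(what, " must be an IRanges of length 1 or a numeric c(start, end)")
}

#' Reference amplicon with coding and splice annotation
#'
#' An \code{Amplicon} holds the reference sequence of the PCR amplicon that
#' spans the CRISPR target region, together with the coordinate annotation in
#' which all downstream mutation calls live: one coding exon, its flanking
#' introns, the two splice windows abutting the exon, and the codon phase of
#' the exon's first base. All coordinates are 1-based closed intervals on the
#' amplicon.
#'
#' @slot id single character identifier.
#' @slot sequence \code{DNAString} over A/C/G/T/N.
#' @slot exon,intron5,intron3,splice5,splice3 \code{IRanges} of length 1.
#'   \code{splice5} must abut the exon on its 5' (left) side and
#'   \code{splice3} on its 3' (right) side; the exon must not overlap either
#'   intron.
#' @slot frameOffset integer 0-2: codon phase of the exon's first base
#'   (number of bases of its first codon contributed by the upstream exon).
#'
#' @examples
#' seq <- paste(rep("ACGT", 75), collapse = "")
#' amp <- Amplicon(seq, exon = c(101, 200), intron5 = c(1, 100),
#'                 intron3 = c(201, 300), splice5 = c(89, 100),
#'                 splice3 = c(201, 212))
#' exonRegion(amp)
#' @name Amplicon-class
#' @aliases Amplicon-class
#' @exportClass Amplicon
setClass("Amplicon",
  slots = c(id = "character", sequence = "DNAString",
            exon = "IRanges", intron5 = "IRanges", intron3 = "IRanges",
            splice5 = "IRanges", splice3 = "IRanges",
            frameOffset = "integer"))

setValidity("Amplicon", function(object) {
  msg <- character(0)
  n <- length(object@sequence)
  bad <- setdiff(uniqueLetters(object@sequence), c("A", "C", "G", "T", "N"))
  if (length(bad))
    msg <- c(msg, paste0("sequence contains letters outside A/C/G/T/N: ",
                         paste(bad, collapse = ",")))
  ivs <- list(exon = object@exon, intron5 = object@intron5,
              intron3 = object@intron3, splice5 = object@splice5,
              splice3 = object@splice3)
  for (nm in names(ivs)) {
    iv <- ivs[[nm]]
    if (length(iv) != 1L) msg <- c(msg, paste0(nm, " must be one interval"))
    else if (start(iv) < 1L || end(iv) > n || width(iv) < 1L)
      msg <- c(msg, paste0(nm, " interval [", start(iv), ",", end(iv),
                           "] out of bounds for a ", n, " nt sequence"))
  }
  if (!length(msg)) {
    ov <- function(a, b) start(a) <= end(b) && start(b) <= end(a)
    if (ov(object@exon, object@intron5))
      msg <- c(msg, "exon overlaps intron5")
    if (ov(object@exon, object@intron3))
      msg <- c(msg, "exon overlaps intron3")
    if (end(object@splice5) + 1L != start(object@exon))
      msg <- c(msg, "splice5 window does not abut the exon on its 5' side")
    if (start(object@splice3) != end(object@exon) + 1L)
      msg <- c(msg, "splice3 window does not abut the exon on its 3' side")
  }
  if (!(object@frameOffset %in% 0:2))
    msg <- c(msg, "frameOffset must be 0, 1 or 2")
  if (length(msg)) msg else TRUE
})

#' Construct an Amplicon
#'
#' @param sequence character or \code{DNAString}; uppercased on input.
#' @param exon,intron5,intron3,splice5,splice3 1-based closed intervals,
#'   each an \code{IRanges} of length 1 or a numeric \code{c(start, end)}.
#' @param id identifier used in reports.
#' @param frameOffset codon phase (0-2) of the exon's first base.
#' @return A validated \code{\link{Amplicon-class}} object; inconsistent
#'   annotation (out-of-bounds, overlapping, or non-abutting intervals) is
#'   rejected with an error naming the offending interval.
#' @examples
#' seq <- paste(rep("ACGT", 75), collapse = "")
#' Amplicon(seq, exon = c(101, 200), intron5 = c(1, 100),
#'          intron3 = c(201, 300), splice5 = c(89, 100),
#'          splice3 = c(201, 212))
#' @export
Amplicon <- function(sequence, exon, intron5, intron3, splice5, splice3,
                     id = "amplicon", frameOffset = 0L) {
  if (is.character(sequence)) sequence <- DNAString(toupper(sequence))
  new("Amplicon", id = id, sequence = sequence,
      exon = .asIRange(exon, "exon"),
      intron5 = .asIRange(intron5, "intron5"),
      intron3 = .asIRange(intron3, "intron3"),
      splice5 = .asIRange(splice5, "splice5"),
      splice3 = .asIRange(splice3, "splice3"),
      frameOffset = as.integer(frameOffset))
}

#' Guide (protospacer) target localized on an amplicon
#'
#' Records where a 20-nt protospacer matches the amplicon, on which strand,
#' its PAM, and the predicted blunt Cas9 cut position. \code{cutPos} is the
#' 1-based reference position immediately 5' (left, in amplicon coordinates)
#' of the cut: the cut falls between \code{cutPos} and \code{cutPos + 1},
#' 3 bp from the PAM-proximal protospacer end.
#'
#' @slot protospacer 20-nt guide sequence (5'->3' on its own strand).
#' @slot strand "+" or "-".
#' @slot start 1-based leftmost amplicon position of the protospacer match.
#' @slot pam the 3-nt PAM observed next to the protospacer.
#' @slot cutPos predicted blunt-cut position (see above).
#' @name GuideTarget-class
#' @exportClass GuideTarget
setClass("GuideTarget",
  slots = c(protospacer = "character", strand = "character",
            start = "integer", pam = "character", cutPos = "integer"))

setValidity("GuideTarget", function(object) {
  msg <- character(0)
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  if (object@start < 1L) msg <- c(msg, "start must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Classification thresholds for editing outcomes
#'
#' Bundles the thresholds used by the disruptive-mutation call and related
#' flags: a read is disruptive when its 5' splice window carries more than
#' \code{spliceChangeMax} changed nucleotides, or when a coding indel leads
#' to a premature stop codon or more than \code{residueChangeMax} residue
#' changes. \code{t7e1MinIndel} is the smallest indel the T7 endonuclease I
#' mismatch-cleavage assay can detect (such events are flagged as
#' T7E1-detectable). \code{nearTargetWindow} is the distance (bp) from the
#' predicted cut within which indels are counted as cut-proximal.
#'
#' @param spliceChangeMax disruptive if 5' splice changes exceed this (default 1).
#' @param residueChangeMax disruptive if residue changes exceed this (default 5).
#' @param minDisruptiveIndelResidues in-frame indels affecting at most this
#'   many residues are never disruptive (default 5).
#' @param t7e1MinIndel minimum indel length detectable by T7E1 (default 2).
#' @param nearTargetWindow cut-proximity window in bp (default 10).
#' @return An \code{EditThresholds} object.
#' @examples
#' editThresholds()
#' @name EditThresholds-class
#' @exportClass EditThresholds
setClass("EditThresholds",
  slots = c(spliceChangeMax = "integer", residueChangeMax = "integer",
            minDisruptiveIndelResidues = "integer", t7e1MinIndel = "integer",
            nearTargetWindow = "integer"))

setValidity("EditThresholds", function(object) {
  vals <- c(object@spliceChangeMax, object@residueChangeMax,
            object@minDisruptiveIndelResidues, object@t7e1MinIndel,
            object@nearTargetWindow)
  if (any(vals < 0L)) "all thresholds must be >= 0" else TRUE
})

#' @rdname EditThresholds-class
#' @export
editThresholds <- function(spliceChangeMax = 1L, residueChangeMax = 5L,
                           minDisruptiveIndelResidues = 5L,
                           t7e1MinIndel = 2L, nearTargetWindow = 10L) {
  new("EditThresholds",
      spliceChangeMax = as.integer(spliceChangeMax),
      residueChangeMax = as.integer(residueChangeMax),
      minDisruptiveIndelResidues = as.integer(minDisruptiveIndelResidues),
      t7e1MinIndel = as.integer(t7e1MinIndel),
      nearTargetWindow = as.integer(nearTargetWindow))
}

#' Affine-gap alignment scoring scheme
#'
#' Scores used by \code{\link{alignReads}}: a gap of length L costs
#' \code{gapOpen + L * gapExtend}. The defaults keep a 50-bp deletion (the
#' largest indel size reported for Cas9 outcomes at this locus class) far
#' cheaper than 50 scattered mismatches, so large deletions stay
#' representable as single events.
#'
#' @param match,mismatch per-base match/mismatch scores.
#' @param gapOpen,gapExtend affine gap penalties (both <= 0, gapOpen < 0).
#' @param maxQueryExcess refuse queries longer than the reference plus this
#'   allowance (guards against mis-paired input).
#' @return An \code{AlignScoring} object.
#' @examples
#' alignScoring()
#' @name AlignScoring-class
#' @exportClass AlignScoring
setClass("AlignScoring",
  slots = c(match = "integer", mismatch = "integer", gapOpen = "integer",
            gapExtend = "integer", maxQueryExcess = "integer"))

setValidity("AlignScoring", function(object) {
  msg <- character(0)
  if (object@match <= 0L) msg <- c(msg, "match must be > 0")
  if (object@mismatch >= 0L) msg <- c(msg, "mismatch must be < 0")
  if (object@gapOpen >= 0L) msg <- c(msg, "gapOpen must be < 0")
  if (object@gapExtend > 0L) msg <- c(msg, "gapExtend must be <= 0")
  if (object@maxQueryExcess < 0L) msg <- c(msg, "maxQueryExcess must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname AlignScoring-class
#' @export
alignScoring <- function(match = 2L, mismatch = -4L, gapOpen = -12L,
                         gapExtend = -1L, maxQueryExcess = 100L) {
  new("AlignScoring", match = as.integer(match),
      mismatch = as.integer(mismatch), gapOpen = as.integer(gapOpen),
      gapExtend = as.integer(gapExtend),
      maxQueryExcess = as.integer(maxQueryExcess))
}

#' Pairwise alignments of reads against one amplicon
#'
#' Container returned by \code{\link{alignReads}}: per-read optimal
#' semi-global alignment score, covered reference interval, CIGAR (with =/X
#' distinction) and the table of left-normalized mutation events.
#'
#' @slot readId character, one per aligned read.
#' @slot score integer alignment scores.
#' @slot range \code{IRanges} of covered reference intervals (1-based closed).
#' @slot cigar character CIGAR strings using =, X, I, D.
#' @slot events data.frame with columns \code{readId}, \code{kind}
#'   (deletion/insertion/substitution), \code{start} (1-based; for insertions
#'   the reference base before which the bases are inserted), \code{length},
#'   \code{alt} (inserted/substituted bases, "" for deletions).
#' @name AmpliconAlignments-class
#' @exportClass AmpliconAlignments
setClass("AmpliconAlignments",
  slots = c(readId = "character", score = "integer", range = "IRanges",
            cigar = "character", events = "data.frame"))

#' Per-sample editing-outcome summary
#'
#' Numeric content of a per-sample editing report: read accounting, the
#' modified fraction, the frameshift/in-frame/noncoding split of modified
#' reads, splice-window modification rates, the disruptive fraction, the
#' signed indel-size histogram, the per-position event profile, and the
#' fraction of indel events near the predicted cut. Category percentages are
#' computed over modified reads only; splice and disruptive percentages over
#' all filter-passing reads. Every percentage's denominator is carried
#' alongside it.
#'
#' @slot sampleId,lineage sample identifier and lineage (cell population
#'   followed across passages).
#' @slot passage passage number (NA when not applicable).
#' @slot nTotal,nMerged,nPassFilter,nModified,nDisruptive read counts.
#' @slot pctModified,pctFrameshift,pctInFrame,pctNoncoding,pctSplice5Modified,pctSplice3Modified,pctDisruptive,pctEventsNearCut
#'   percentages (0-100; NA when the denominator is 0).
#' @slot indelHistogram data.frame(size, count) of signed indel sizes, with a
#'   0 bin counting filter-passing reads without indels.
#' @slot positionalProfile data.frame(position, insertion, deletion,
#'   substitution) of per-reference-position event coverage.
#' @slot isEmpty TRUE when no read passed the region filter.
#' @name SampleSummary-class
#' @exportClass SampleSummary
setClass("SampleSummary",
  slots = c(sampleId = "character", lineage = "character",
            passage = "integer",
            nTotal = "integer", nMerged = "integer", nPassFilter = "integer",
            nModified = "integer", nDisruptive = "integer",
            pctModified = "numeric", pctFrameshift = "numeric",
            pctInFrame = "numeric", pctNoncoding = "numeric",
            pctSplice5Modified = "numeric", pctSplice3Modified = "numeric",
            pctDisruptive = "numeric", pctEventsNearCut = "numeric",
            indelHistogram = "data.frame", positionalProfile = "data.frame",
            isEmpty = "logical"))

setValidity("SampleSummary", function(object) {
  msg <- character(0)
  if (object@nPassFilter > object@nMerged || object@nMerged > object@nTotal)
    msg <- c(msg, "need nPassFilter <= nMerged <= nTotal")
  pcts <- c(object@pctModified, object@pctFrameshift, object@pctInFrame,
            object@pctNoncoding, object@pctSplice5Modified,
            object@pctSplice3Modified, object@pctDisruptive,
            object@pctEventsNearCut)
  pcts <- pcts[!is.na(pcts)]
  if (any(pcts < 0 | pcts > 100))
    msg <- c(msg, "percentages must lie in [0, 100]")
  if (object@nModified > 0L) {
    s <- object@pctFrameshift + object@pctInFrame + object@pctNoncoding
    if (!is.na(s) && abs(s - 100) > 1e-6)
      msg <- c(msg, "category percentages of modified reads must sum to 100")
  }
  if (length(msg)) msg else TRUE
})

#' Cross-passage stability report for the disruptive fraction
#'
#' Produced by \code{\link{comparePassages}}: per-passage disruptive
#' fractions with 95\% Wilson score intervals, all pairwise two-proportion
#' z-tests (raw and Holm-adjusted p-values), the maximum absolute difference
#' between passages, and the overall stability call (stable when no
#' Holm-adjusted pairwise test rejects at \code{alpha}).
#'
#' @slot lineage lineage the passages belong to.
#' @slot alpha family-wise significance level of the stability call.
#' @slot perPassage data.frame(passage, k, n, proportion, lower, upper).
#' @slot pairwise data.frame(passage1, passage2, z, pValue, pAdjusted).
#' @slot maxAbsDiff largest absolute difference between passage proportions.
#' @slot stable logical stability call.
#' @name StabilityReport-class
#' @exportClass StabilityReport
setClass("StabilityReport",
  slots = c(lineage = "character", alpha = "numeric",
            perPassage = "data.frame", pairwise = "data.frame",
            maxAbsDiff = "numeric", stable = "logical"))

setValidity("StabilityReport", function(object) {
  pp <- object@perPassage
  if (nrow(pp) &&
      any(pp$proportion < pp$lower - 1e-12 | pp$proportion > pp$upper + 1e-12))
    "Wilson intervals must contain their point estimates" else TRUE
})
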