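#' @include AllClasses.R
NULL

#' Accessors for Amplicon and GuideTarget objects
#'
#' @param x an \code{\link{Amplicon-class}} or
#'   \code{\link{GuideTarget-class}} object.
#' @param side which splice window, "5" or "3".
#' @return \code{ampliconSeq}: the reference \code{DNAString};
#'   \code{exonRegion}/\code{intronRegion}/\code{spliceWindow}: an
#'   \code{IRanges}; \code{frameOffset}, \code{cutSite}: an integer;
#'   \code{protospacerSeq}: a character string.
#' @examples
#' toy <- makeToyAmplicon(seed = 1)
#' exonRegion(toy$amplicon)
#' cutSite(toy$guide)
#' @name amplicon-accessors
NULL

#' @rdname amplicon-accessors
#' @export
setGeneric("ampliconSeq", function(x) standardGeneric("ampliconSeq"))
#' @rdname amplicon-accessors
#' @export
setGeneric("exonRegion", function(x) standardGeneric("exonRegion"))
#' @rdname amplicon-accessors
#' @export
setGeneric("intronRegion", function(x, side = "5") standardGeneric("intronRegion"))
#' @rdname amplicon-accessors
#' @export
setGeneric("spliceWindow", function(x, side = "5") standardGeneric("spliceWindow"))
#' @rdname amplicon-accessors
#' @export
setGeneric("frameOffset", function(x) standardGeneric("frameOffset"))
#' @rdname amplicon-accessors
#' @export
setGeneric("cutSite", function(x) standardGeneric("cutSite"))
#' @rdname amplicon-accessors
#' @export
setGeneric("protospacerSeq", function(x) standardGeneric("protospacerSeq"))

#' @rdname amplicon-accessors
setMethod("ampliconSeq", "Amplicon", function(x) x@sequence)
#' @rdname amplicon-accessors
setMethod("exonRegion", "Amplicon", function(x) x@exon)
#' @rdname amplicon-accessors
setMethod("intronRegion", "Amplicon", function(x, side = "5") {
  side <- match.arg(as.character(side), c("5", "3"))
  if (side == "5") x@intron5 else x@intron3
})
#' @rdname amplicon-accessors
setMethod("spliceWindow", "Amplicon", function(x, side = "5") {
  side <- match.arg(as.character(side), c("5", "3"))
  if (side == "5") x@splice5 else x@splice3
})
#' @rdname amplicon-accessors
setMethod("frameOffset", "Amplicon", function(x) x@frameOffset)
#' @rdname amplicon-accessors
setMethod("cutSite", "GuideTarget", function(x) x@cutPos)
#' @rdname amplicon-accessors
setMethod("protospacerSeq", "GuideTarget", function(x) x@protospacer)

setMethod("show", "Amplicon", function(object) {
  cat("Amplicon \"", object@id, "\": ", length(object@sequence), " nt\n",
      sep = "")
  fmt <- function(iv) paste0("[", start(iv), ", ", end(iv), "]")
  cat("  exon    ", fmt(object@exon),
      "  (frame offset ", object@frameOffset, ")\n", sep = "")
  cat("  introns ", fmt(object@intron5), " / ", fmt(object@intron3), "\n",
      sep = "")
  cat("  splice windows 5' ", fmt(object@splice5), " = ",
      as.character(object@sequence[object@splice5]),
      " ; 3' ", fmt(object@splice3), "\n", sep = "")
})

setMethod("show", "GuideTarget", function(object) {
  cat("GuideTarget ", object@protospacer, " (", object@strand,
      "), start ", object@start, ", PAM ", object@pam,
      ", predicted cut after position ", object@cutPos, "\n", sep = "")
})

setMethod("show", "EditThresholds", function(object) {
  cat("EditThresholds: splice>", object@spliceChangeMax,
      ", residues>", object@residueChangeMax,
      ", min disruptive indel residues ", object@minDisruptiveIndelResidues,
      ", T7E1 >= ", object@t7e1MinIndel,
      " nt, near-target window ", object@nearTargetWindow, " bp\n", sep = "")
})

setMethod("show", "AlignScoring", function(object) {
  cat("AlignScoring: match +", object@match, ", mismatch ", object@mismatch,
      ", gap ", object@gapOpen, " + ", object@gapExtend, "/nt\n", sep = "")
})

setMethod("show", "AmpliconAlignments", function(object) {
  cat("AmpliconAlignments: ", length(object@readId), " reads, ",
      nrow(object@events), " events\n", sep = "")
  if (length(object@readId)) {
    cat("  score range [", min(object@score), ", ", max(object@score),
        "]; covered ref [", min(start(object@range)), ", ",
        max(end(object@range)), "]\n", sep = "")
  }
})

setMethod("show", "SampleSummary", function(object) {
  cat("SampleSummary \"", object@sampleId, "\" (lineage ", object@lineage,
      ", passage ", object@passage, ")\n", sep = "")
  cat("  reads: ", object@nTotal, " total, ", object@nMerged, " merged, ",
      object@nPassFilter, " pass region filter\n", sep = "")
  if (object@isEmpty) { cat("  <no filter-passing reads>\n"); return(invisible(NULL)) }
  p <- function(x) formatC(x, digits = 2, format = "f")
  cat("  modified ", p(object@pctModified), "% (", object@nModified, "/",
      object@nPassFilter, ")\n", sep = "")
  cat("  of modified: frameshift ", p(object@pctFrameshift),
      "%, in-frame ", p(object@pctInFrame),
      "%, noncoding ", p(object@pctNoncoding), "%\n", sep = "")
  cat("  splice windows modified: 5' ", p(object@pctSplice5Modified),
      "%, 3' ", p(object@pctSplice3Modified), "%\n", sep = "")
  cat("  disruptive ", p(object@pctDisruptive), "% (", object@nDisruptive,
      "/", object@nPassFilter, ")", sep = "")
  if (!is.na(object@pctEventsNearCut))
    cat("; indel events near cut ", p(object@pctEventsNearCut), "%", sep = "")
  cat("\n")
})

setMethod("show", "StabilityReport", function(object) {
  cat("StabilityReport for lineage \"", object@lineage, "\" (alpha = ",
      object@alpha, ")\n", sep = "")
  print(object@perPassage, row.names = FALSE)
  cat("  max |difference| = ", formatC(object@maxAbsDiff, digits = 4,
      format = "f"), "; ", sep = "")
  cat(if (object@stable) "STABLE" else "NOT stable",
      " (no Holm-adjusted pairwise p <", object@alpha, "rejects)\n")
})

#' Extract alignment results
#'
#' @param x an \code{\link{AmpliconAlignments-class}} object.
#' @return \code{alignmentEvents}: the per-read mutation-event table
#'   (columns readId, kind, start, length, alt); \code{alignmentScores}:
#'   named integer scores; \code{alignedRanges}: named \code{IRanges} of
#'   covered reference intervals; \code{alignmentCigars}: named CIGARs.
#' @examples
#' toy <- makeToyAmplicon(seed = 1)
#' aln <- alignReads(as.character(ampliconSeq(toy$amplicon)), toy$amplicon)
#' alignmentScores(aln)
#' @name alignment-accessors
NULL

#' @rdname alignment-accessors
#' @export
alignmentEvents <- function(x) x@events
#' @rdname alignment-accessors
#' @export
alignmentScores <- function(x) setNames(x@score, x@readId)
#' @rdname alignment-accessors
#' @export
alignedRanges <- function(x) setNames(x@range, x@readId)
#' @rdname alignment-accessors
#' @export
alignmentCigars <- function(x) setNames(x@cigar, x@readId)

#' Summary accessors
#'
#' @param x a \code{\link{SampleSummary-class}} object (for
#'   \code{summaryRow}) or a \code{\link{StabilityReport-class}} (for
#'   \code{isStable}).
#' @return \code{summaryRow}: a one-row data.frame of all counts and
#'   percentages (denominators included); \code{isStable}: logical.
#' @export
summaryRow <- function(x) {
  stopifnot(is(x, "SampleSummary"))
  data.frame(sampleId = x@sampleId, lineage = x@lineage, passage = x@passage,
             nTotal = x@nTotal, nMerged = x@nMerged,
             nPassFilter = x@nPassFilter, nModified = x@nModified,
             nDisruptive = x@nDisruptive,
             pctModified = x@pctModified, pctFrameshift = x@pctFrameshift,
             pctInFrame = x@pctInFrame, pctNoncoding = x@pctNoncoding,
             pctSplice5Modified = x@pctSplice5Modified,
             pctSplice3Modified = x@pctSplice3Modified,
             pctDisruptive = x@pctDisruptive,
             pctEventsNearCut = x@pctEventsNearCut,
             stringsAsFactors = FALSE)
}

#' @rdname summaryRow
#' @export
isStable <- function(x) {
  stopifnot(is(x, "StabilityReport"))
  x@stable
}
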