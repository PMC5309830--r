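#' @include AllClasses.R
NULL

#' Align reads to the reference amplicon
#'
#' Optimal semi-global affine-gap alignment of each read against the
#' amplicon: reference end gaps are free (reads are amplicon-contained by
#' design), the full read must align, and a gap of length L costs
#' \code{gapOpen + L * gapExtend}. Traceback is deterministic (match over
#' deletion over insertion at equal score; smallest reference end on
#' endpoint ties) and indels are left-shifted to the smallest reference
#' coordinate (VCF-style), so event positions are convention-free and
#' reproducible. Runs of adjacent gap columns of the same kind become single
#' indel events; runs of mismatch columns become single substitution events.
#'
#' @param reads character vector, \code{DNAStringSet} or
#'   \code{QualityScaledDNAStringSet}.
#' @param amplicon an \code{\link{Amplicon-class}}.
#' @param scoring an \code{\link{alignScoring}} scheme.
#' @return An \code{\link{AmpliconAlignments-class}} object.
#' @examples
#' toy <- makeToyAmplicon(seed = 1)
#' ref <- as.character(ampliconSeq(toy$amplicon))
#' aln <- alignReads(substr(ref, 41, 340), toy$amplicon)
#' alignmentScores(aln)       # 300 matches
#' alignedRanges(aln)
#' @export
alignReads <- function(reads, amplicon, scoring = alignScoring()) {
  stopifnot(is(amplicon, "Amplicon"), is(scoring, "AlignScoring"))
  ids <- names(reads)
  seqs <- toupper(as.character(reads))
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(seqs))
  if (length(seqs) == 0L)
    return(new("AmpliconAlignments", readId = character(0),
               score = integer(0), range = IRanges(), cigar = character(0),
               events = .emptyEvents()))
  if (any(nchar(seqs) == 0L)) stop("empty read(s) in input")
  ref <- as.character(amplicon@sequence)
  tooLong <- nchar(seqs) > nchar(ref) + scoring@maxQueryExcess
  if (any(tooLong))
    stop(sum(tooLong), " read(s) exceed the reference length plus the ",
         "maximum insert allowance (", scoring@maxQueryExcess, " nt)")
  # exact-substring fast path: a full-length match scores 2*match*len, the
  # provable optimum, and the leftmost occurrence equals the DP tie-break
  n <- length(seqs)
  exactAt <- vapply(seqs, function(q) regexpr(q, ref, fixed = TRUE)[1], 1L,
                    USE.NAMES = FALSE)
  score <- integer(n); refStart <- integer(n); refEnd <- integer(n)
  cigar <- character(n)
  ex <- exactAt > 0L
  if (any(ex)) {
    w <- nchar(seqs[ex])
    score[ex] <- scoring@match * w
    refStart[ex] <- exactAt[ex]
    refEnd[ex] <- exactAt[ex] + w - 1L
    cigar[ex] <- paste0(w, "=")
  }
  if (any(!ex)) {
    res <- cpp_align_reads(seqs[!ex], ref, scoring@match, scoring@mismatch,
                           scoring@gapOpen, scoring@gapExtend)
    score[!ex] <- res$score
    refStart[!ex] <- res$refStart
    refEnd[!ex] <- res$refEnd
    cigar[!ex] <- res$cigar
    evIdx <- which(!ex)[res$evRead]
  } else {
    res <- list(evRead = integer(0), evKind = integer(0),
                evStart = integer(0), evLen = integer(0),
                evAlt = character(0))
    evIdx <- integer(0)
  }
  events <- data.frame(readId = ids[evIdx],
                       kind = .EVENT_KINDS[res$evKind],
                       start = res$evStart, length = res$evLen,
                       alt = res$evAlt, stringsAsFactors = FALSE)
  events <- events[order(match(events$readId, ids), events$start), ,
                   drop = FALSE]
  rownames(events) <- NULL
  new("AmpliconAlignments", readId = ids, score = score,
      range = IRanges(refStart, refEnd), cigar = cigar,
      events = events)
}

.emptyEvents <- function() {
  data.frame(readId = character(0), kind = character(0), start = integer(0),
             length = integer(0), alt = character(0),
             stringsAsFactors = FALSE)
}

#' Region filter: contiguous coverage of splice window and exon
#'
#' A read enters mutation-frequency evaluation only when its aligned
#' reference span contains both the 5' splice window and the whole exon.
#' Coverage is positional: a read whose span covers the window but whose
#' splice site is deleted or substituted passes (that is a splice mutation,
#' not a filter failure); requiring the literal motif would exclude exactly
#' the reads whose splice disruption is being counted. Set
#' \code{requireMotif = TRUE} for the stricter literal-motif alternative.
#'
#' @param alignments an \code{\link{AmpliconAlignments-class}}.
#' @param amplicon the \code{\link{Amplicon-class}} aligned against.
#' @param requireMotif also require the read to carry the exact reference
#'   splice-window sequence (default FALSE).
#' @param reads original read sequences; only needed when
#'   \code{requireMotif = TRUE}.
#' @return Named logical vector, one element per read.
#' @examples
#' toy <- makeToyAmplicon(seed = 1)
#' ref <- as.character(ampliconSeq(toy$amplicon))
#' aln <- alignReads(c(full = ref, part = substr(ref, 160, 440)), toy$amplicon)
#' passesRegionFilter(aln, toy$amplicon)
#' @export
passesRegionFilter <- function(alignments, amplicon, requireMotif = FALSE,
                               reads = NULL) {
  stopifnot(is(alignments, "AmpliconAlignments"), is(amplicon, "Amplicon"))
  lo <- min(start(amplicon@splice5), start(amplicon@exon))
  hi <- max(end(amplicon@splice5), end(amplicon@exon))
  ok <- start(alignments@range) <= lo & end(alignments@range) >= hi
  if (requireMotif) {
    if (is.null(reads)) stop("requireMotif = TRUE needs the read sequences")
    motif <- as.character(amplicon@sequence[amplicon@splice5])
    ok <- ok & grepl(motif, toupper(as.character(reads)), fixed = TRUE)
  }
  setNames(ok, alignments@readId)
}

#' Write alignments as SAM for inspection in standard viewers
#'
#' Minimal single-reference SAM export of \code{\link{alignReads}} results
#' (CIGARs keep the =/X distinction).
#'
#' @param alignments an \code{\link{AmpliconAlignments-class}}.
#' @param reads the aligned reads (sequences written into the SAM records).
#' @param amplicon the reference \code{\link{Amplicon-class}}.
#' @param file output path.
#' @return The path, invisibly.
#' @export
writeSam <- function(alignments, reads, amplicon, file) {
  stopifnot(is(alignments, "AmpliconAlignments"), is(amplicon, "Amplicon"))
  seqs <- toupper(as.character(reads))
  if (length(seqs) != length(alignments@readId))
    stop("reads and alignments disagree in length")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               paste0("@SQ\tSN:", amplicon@id, "\tLN:",
                      length(amplicon@sequence))), con)
  writeLines(paste(alignments@readId, 0L, amplicon@id,
                   start(alignments@range), 60L, alignments@cigar,
                   "*", 0L, 0L, seqs, "*", sep = "\t"), con)
  invisible(file)
}
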