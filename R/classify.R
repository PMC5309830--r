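#' @include events.R
NULL

# ---- shared event arithmetic -------------------------------------------------

# per-event signed exonic indel contribution: +inserted nt at exon-internal
# junctions, -deleted nt lying inside the exon, 0 for substitutions
.exonicIndelSigned <- function(events, exon) {
  lo <- start(exon); hi <- end(exon)
  out <- integer(nrow(events))
  del <- events$kind == "deletion"
  out[del] <- -pmax(0L, pmin(events$start[del] + events$length[del] - 1L, hi) -
                         pmax(events$start[del], lo) + 1L)
  ins <- events$kind == "insertion" & events$start > lo & events$start <= hi
  out[ins] <- events$length[ins]
  out
}

# per-read aggregation of the event table; readIds fixes the read universe
.perReadEventStats <- function(events, amplicon, readIds) {
  .checkEvents(events)
  exon <- amplicon@exon
  signedL <- .exonicIndelSigned(events, exon)
  exonOv <- .eventIntervalOverlap(events, start(exon), end(exon))
  isIndel <- events$kind != "substitution"
  agg <- function(x) {
    out <- numeric(length(readIds))
    if (nrow(events)) {
      r <- rowsum(as.numeric(x), events$readId)
      hit <- match(rownames(r), readIds)
      out[hit[!is.na(hit)]] <- r[!is.na(hit), 1]
    }
    as.integer(out)
  }
  data.frame(
    readId = readIds,
    nEvents = agg(rep(1L, nrow(events))),
    netExonIndel = agg(signedL),
    codingIndel = agg(isIndel & exonOv > 0L) > 0L,
    anyExonEvent = agg(exonOv > 0L) > 0L,
    anyIndel = agg(isIndel) > 0L,
    splice5Changes = agg(.spliceChangeContrib(events, amplicon@splice5)),
    splice3Changes = agg(.spliceChangeContrib(events, amplicon@splice3)),
    stringsAsFactors = FALSE)
}

# nucleotide changes an event contributes to a splice window: deleted or
# substituted reference nt inside the window, plus inserted nt at junctions
# strictly inside it
.spliceChangeContrib <- function(events, window) {
  .eventIntervalOverlap(events, start(window), end(window))
}

# ---- coding-impact classification -------------------------------------------

.codingCategories <- function(events, amplicon, readIds) {
  stats <- .perReadEventStats(events, amplicon, readIds)
  ifelse(stats$nEvents == 0L, "unmodified",
    ifelse(stats$codingIndel,
      ifelse(stats$netExonIndel %% 3L != 0L, "frameshift", "in_frame"),
      ifelse(stats$anyExonEvent, "in_frame", "noncoding")))
}

#' Coding-impact category of one read's events
#'
#' Implements the frame rule: the signed lengths of all indel events
#' overlapping the exon are summed (insertions at exon-internal junctions
#' count positive, deleted exonic nucleotides negative); a nonzero set of
#' exon-overlapping indels whose net length is not divisible by three is a
#' frameshift, otherwise in-frame. Reads whose events all lie outside the
#' exon are noncoding; reads without events are unmodified.
#' Substitution-only reads touching the exon are modified but keep the
#' reading frame, so they classify as in-frame and are judged by protein
#' consequence, never as frameshift.
#'
#' @param events event table for a single read (or with a single readId).
#' @param amplicon the \code{\link{Amplicon-class}}.
#' @return One of "unmodified", "frameshift", "in_frame", "noncoding".
#' @examples
#' toy <- makeToyAmplicon(seed = 1)
#' ev <- data.frame(readId = "r", kind = "deletion",
#'                  start = start(exonRegion(toy$amplicon)) + 10L,
#'                  length = 1L, alt = "")
#' classifyCodingImpact(ev, toy$amplicon)  # frameshift
#' @export
classifyCodingImpact <- function(events, amplicon) {
  stopifnot(is(amplicon, "Amplicon"))
  ids <- unique(events$readId)
  if (length(ids) > 1L) stop("events belong to more than one read")
  if (length(ids) == 0L) ids <- "read"
  .codingCategories(events, amplicon, ids)
}

#' Nucleotide changes inside a splice window
#'
#' Number of reference nucleotides of the window that are deleted or
#' substituted, plus the number of nucleotides inserted at junctions
#' strictly inside the window.
#'
#' @param events event table (any number of reads; contributions are summed).
#' @param window an \code{IRanges} of length 1, typically
#'   \code{spliceWindow(amplicon, "5")}.
#' @return Integer count.
#' @examples
#' toy <- makeToyAmplicon(seed = 1)
#' w <- spliceWindow(toy$amplicon, "5")
#' ev <- data.frame(readId = "r", kind = "substitution",
#'                  start = start(w) + 2L, length = 1L, alt = "A")
#' countSpliceChanges(ev, w)  # 1
#' @export
countSpliceChanges <- function(events, window) {
  .checkEvents(events)
  stopifnot(is(window, "IRanges"), length(window) == 1L)
  sum(.spliceChangeContrib(events, window))
}

# ---- protein consequence ----------------------------------------------------

# apply non-overlapping, sorted events to a reference string; returns the
# mutant string and the mutant coordinates of the requested reference
# positions (a position inside a deletion lifts to the first mutant position
# at or after the deleted block)
.applyEvents <- function(refSeq, events, liftPos = integer(0)) {
  if (nrow(events) > 1L) {
    events <- events[order(events$start, match(events$kind, .EVENT_KINDS)), ,
                     drop = FALSE]
    endPos <- ifelse(events$kind == "insertion", events$start - 1L,
                     events$start + events$length - 1L)
    if (any(events$start[-1L] <= endPos[-nrow(events)]))
      stop("overlapping events cannot be applied")
  }
  n <- nchar(refSeq)
  pieces <- character(0)
  cursor <- 1L
  lift <- liftPos
  shift <- 0L
  for (i in seq_len(nrow(events))) {
    s <- events$start[i]; L <- events$length[i]; k <- events$kind[i]
    if (k == "insertion") {
      if (s < 1L || s > n + 1L) stop("insertion junction out of bounds")
      pieces <- c(pieces, substr(refSeq, cursor, s - 1L), events$alt[i])
      lift <- ifelse(liftPos >= s, lift + L, lift)
      shift <- shift + L
      cursor <- s
    } else if (k == "deletion") {
      if (s < 1L || s + L - 1L > n) stop("deletion out of bounds")
      pieces <- c(pieces, substr(refSeq, cursor, s - 1L))
      inDel <- liftPos >= s & liftPos <= s + L - 1L
      lift <- ifelse(inDel, s + shift, ifelse(liftPos > s + L - 1L, lift - L, lift))
      shift <- shift - L
      cursor <- s + L
    } else {
      if (s < 1L || s + L - 1L > n) stop("substitution out of bounds")
      pieces <- c(pieces, substr(refSeq, cursor, s - 1L), events$alt[i])
      cursor <- s + L
    }
  }
  pieces <- c(pieces, substr(refSeq, cursor, n))
  list(seq = paste(pieces, collapse = ""), lift = as.integer(lift))
}

# translate a DNA string (truncating the trailing partial codon); stops as "*"
.translateDNA <- function(seq) {
  nc <- 3L * (nchar(seq) %/% 3L)
  if (nc == 0L) return("")
  codons <- substring(seq, seq(1L, nc, 3L), seq(3L, nc, 3L))
  aa <- GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

#' Protein-level consequence of one read's events
#'
#' Reconstructs the mutant sequence, lifts the exon boundaries through the
#' events, and translates in the exon's frame. When the net exonic indel
#' length is a multiple of three the mutant exon alone is translated; when
#' the frame is shifted, translation continues past the exon into the
#' downstream reference sequence until a stop codon or the sequence end
#' (pre-mRNA read-through; downstream exons are outside the amplicon), which
#' is how frameshift-induced stops are caught. \code{prematureStop} is TRUE
#' when that translation hits a stop while the reference exon translation
#' has none; \code{residueChanges} is the Levenshtein distance between the
#' reference exon peptide and the mutant peptide truncated at its first
#' stop.
#'
#' @param events event table for a single read.
#' @param amplicon the \code{\link{Amplicon-class}}.
#' @return list(prematureStop = logical, residueChanges = integer).
#' @examples
#' toy <- makeToyAmplicon(seed = 1)
#' es <- start(exonRegion(toy$amplicon))
#' del3 <- data.frame(readId = "r", kind = "deletion", start = es + 3L,
#'                    length = 3L, alt = "")
#' proteinConsequence(del3, toy$amplicon)  # one residue removed, no stop
#' @export
proteinConsequence <- function(events, amplicon) {
  stopifnot(is(amplicon, "Amplicon"))
  .checkEvents(events)
  if (length(unique(events$readId)) > 1L)
    stop("events belong to more than one read")
  refSeq <- as.character(amplicon@sequence)
  es <- start(amplicon@exon); ee <- end(amplicon@exon)
  off <- (3L - amplicon@frameOffset) %% 3L  # bases completing the split codon
  refPep <- .translateDNA(substr(refSeq, es + off, ee))
  refHasStop <- grepl("*", refPep, fixed = TRUE)
  if (nrow(events) == 0L)
    return(list(prematureStop = FALSE, residueChanges = 0L))

  mut <- .applyEvents(refSeq, events, liftPos = c(es, ee))
  mes <- mut$lift[1]; mee <- mut$lift[2]
  netL <- sum(.exonicIndelSigned(events, amplicon@exon))
  if (netL %% 3L == 0L) {
    pep <- .translateDNA(substr(mut$seq, mes + off, mee))
  } else {
    pep <- .translateDNA(substr(mut$seq, mes + off, nchar(mut$seq)))
  }
  stopAt <- regexpr("*", pep, fixed = TRUE)
  premature <- stopAt > 0L && !refHasStop
  mutPep <- if (stopAt > 0L) substr(pep, 1L, stopAt - 1L) else pep
  list(prematureStop = premature,
       residueChanges = as.integer(adist(refPep, mutPep)))
}

# ---- disruptive call and T7E1 flag ------------------------------------------

#' Disruptive-mutation call
#'
#' A read's mutations are potentially disruptive when the 5' splice window
#' carries more than \code{spliceChangeMax} changed nucleotides, or when a
#' coding (exon-overlapping) indel leads to a premature stop codon or more
#' than \code{residueChangeMax} residue changes. Explicitly never
#' disruptive: substitution-only reads (SNPs), 3' splice window changes, and
#' in-frame indels affecting at most \code{minDisruptiveIndelResidues}
#' residues.
#'
#' @param outcomes data.frame with columns \code{splice5Changes},
#'   \code{codingIndel}, \code{prematureStop}, \code{residueChanges} (as
#'   produced by \code{\link{classifyReads}}), or a single-row equivalent.
#' @param thresholds an \code{\link{editThresholds}} object.
#' @return Logical vector, one element per row of \code{outcomes}.
#' @examples
#' out <- data.frame(splice5Changes = c(2L, 0L), codingIndel = c(FALSE, TRUE),
#'                   prematureStop = c(FALSE, TRUE), residueChanges = c(0L, 9L))
#' isDisruptive(out)  # TRUE TRUE
#' @export
isDisruptive <- function(outcomes, thresholds = editThresholds()) {
  stopifnot(is(thresholds, "EditThresholds"))
  outcomes$splice5Changes > thresholds@spliceChangeMax |
    (outcomes$codingIndel &
       (outcomes$prematureStop |
          outcomes$residueChanges > thresholds@residueChangeMax))
}

#' T7E1 detectability of a read's events
#'
#' The T7 endonuclease I mismatch-cleavage assay only recognises indels of
#' at least \code{t7e1MinIndel} (default 2) nucleotides; this flags reads
#' carrying at least one such event. Substitutions never qualify.
#'
#' @param events event table (any number of reads).
#' @param thresholds an \code{\link{editThresholds}} object.
#' @return Named logical vector, one element per distinct readId in
#'   \code{events}.
#' @examples
#' ev <- data.frame(readId = c("a", "b"), kind = c("insertion", "deletion"),
#'                  start = c(5L, 9L), length = c(1L, 2L), alt = c("G", ""))
#' t7e1Detectable(ev)  # a FALSE, b TRUE
#' @export
t7e1Detectable <- function(events, thresholds = editThresholds()) {
  .checkEvents(events)
  ids <- unique(events$readId)
  hit <- events$kind != "substitution" &
    events$length >= thresholds@t7e1MinIndel
  setNames(ids %in% events$readId[hit], ids)
}

# ---- per-read driver ---------------------------------------------------------

#' Classify every aligned read
#'
#' Runs the full per-read outcome classification: region filter, coding
#' category, splice-window change counts, protein consequence (for reads
#' with events), the disruptive call, and T7E1 detectability.
#'
#' @param alignments an \code{\link{AmpliconAlignments-class}} from
#'   \code{\link{alignReads}}.
#' @param amplicon the \code{\link{Amplicon-class}}.
#' @param thresholds an \code{\link{editThresholds}} object.
#' @return data.frame with one row per read: readId, refStart, refEnd,
#'   passesFilter, nEvents, modified, category, codingIndel, splice5Changes,
#'   splice3Changes, prematureStop, residueChanges, disruptive,
#'   t7e1Detectable. Unmodified reads have zero counts and all flags FALSE.
#' @examples
#' toy <- makeToyAmplicon(seed = 1)
#' sim <- simulateReads(toy$amplicon, toy$guide,
#'                      simulationConfig(nReads = 20, subErrorRate = 0, seed = 3))
#' m <- mergePairs(sim$reads1, sim$reads2)
#' aln <- alignReads(m$reads, toy$amplicon)
#' table(classifyReads(aln, toy$amplicon)$category)
#' @export
classifyReads <- function(alignments, amplicon,
                          thresholds = editThresholds()) {
  stopifnot(is(alignments, "AmpliconAlignments"), is(amplicon, "Amplicon"),
            is(thresholds, "EditThresholds"))
  ids <- alignments@readId
  events <- alignments@events
  stats <- .perReadEventStats(events, amplicon, ids)
  category <- .codingCategories(events, amplicon, ids)

  t7 <- events$kind != "substitution" & events$length >= thresholds@t7e1MinIndel
  t7byRead <- ids %in% events$readId[t7]

  prematureStop <- logical(length(ids))
  residueChanges <- integer(length(ids))
  needPep <- which(stats$anyExonEvent | stats$codingIndel)
  if (length(needPep)) {
    evSplit <- split(seq_len(nrow(events)), factor(events$readId, levels = ids))
    for (i in needPep) {
      pc <- proteinConsequence(events[evSplit[[i]], , drop = FALSE], amplicon)
      prematureStop[i] <- pc$prematureStop
      residueChanges[i] <- pc$residueChanges
    }
  }

  out <- data.frame(
    readId = ids,
    refStart = start(alignments@range), refEnd = end(alignments@range),
    passesFilter = unname(passesRegionFilter(alignments, amplicon)),
    nEvents = stats$nEvents,
    modified = stats$nEvents > 0L,
    category = category,
    codingIndel = stats$codingIndel,
    splice5Changes = stats$splice5Changes,
    splice3Changes = stats$splice3Changes,
    prematureStop = prematureStop,
    residueChanges = residueChanges,
    t7e1Detectable = t7byRead,
    stringsAsFactors = FALSE)
  out$disruptive <- isDisruptive(out, thresholds)
  out
}
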