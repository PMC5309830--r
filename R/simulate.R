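#' @include classify.R
NULL

.STOP_FREE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                             c("TAA", "TAG", "TGA"))

.randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a random toy amplicon with an embedded guide target
#'
#' Generates a random amplicon with the canonical layout used throughout the
#' package's validation: a 5' intron whose last 12 nt are the splice-donor
#' motif TTAAAAGCTTCC, a stop-codon-free coding exon (frame offset 0), a 3'
#' intron whose first 12 nt form the 3' splice window, and exactly one
#' NGG-adjacent protospacer. The protospacer is taken from the generated
#' exon sequence (its PAM's GG is written in), starting \code{guideExonOffset}
#' nt into the exon, so the predicted cut falls \code{guideExonOffset + 16}
#' nt into the exon - close enough to the 5' splice window that large
#' cut-centred deletions occasionally clip it, as seen in real editing data.
#' Generation retries until all amplicon invariants hold and the guide is
#' unique; two different seeds give different sequences with the same
#' structure.
#'
#' @param seed integer seed (the global RNG state is restored afterwards).
#' @param intron5Len,exonLen,intron3Len segment lengths; \code{exonLen} must
#'   be a multiple of 3 and >= guideExonOffset + 22, \code{intron5Len} >= 12,
#'   \code{intron3Len} >= 12.
#' @param spliceMotif content of the 12-nt 5' splice window.
#' @param guideExonOffset 1-based exon position of the protospacer's first
#'   base (default 3).
#' @param maxTries abort after this many rejected candidates.
#' @return list(amplicon = \code{\link{Amplicon-class}},
#'   guide = \code{\link{GuideTarget-class}}).
#' @examples
#' toy <- makeToyAmplicon(seed = 1)
#' toy$amplicon
#' toy$guide
#' @export
makeToyAmplicon <- function(seed = 1L, intron5Len = 150L, exonLen = 150L,
                            intron3Len = 140L,
                            spliceMotif = "TTAAAAGCTTCC",
                            guideExonOffset = 3L, maxTries = 100L) {
  stopifnot(intron5Len >= nchar(spliceMotif), intron3Len >= 12L,
            exonLen %% 3L == 0L, exonLen >= guideExonOffset + 22L)
  .withSeed(seed, {
    for (try in seq_len(maxTries)) {
      i5 <- .randomDNA(intron5Len)
      substr(i5, intron5Len - nchar(spliceMotif) + 1L, intron5Len) <- spliceMotif
      exon <- paste(sample(.STOP_FREE_CODONS, exonLen / 3L, replace = TRUE),
                    collapse = "")
      # write the PAM's GG immediately 3' of the protospacer
      pamPos <- guideExonOffset + 20L
      substr(exon, pamPos + 1L, pamPos + 2L) <- "GG"
      codons <- substring(exon, seq(1L, exonLen, 3L), seq(3L, exonLen, 3L))
      if (any(codons %in% c("TAA", "TAG", "TGA"))) next
      i3 <- .randomDNA(intron3Len)
      seq <- paste0(i5, exon, i3)
      es <- intron5Len + 1L
      amp <- Amplicon(seq,
                      exon = c(es, es + exonLen - 1L),
                      intron5 = c(1L, intron5Len),
                      intron3 = c(es + exonLen, nchar(seq)),
                      splice5 = c(es - nchar(spliceMotif), es - 1L),
                      splice3 = c(es + exonLen, es + exonLen + 11L),
                      id = sprintf("toy_amplicon_seed%d", seed),
                      frameOffset = 0L)
      proto <- substr(exon, guideExonOffset, guideExonOffset + 19L)
      guide <- tryCatch(locateGuide(amp, proto), error = function(e) NULL)
      if (is.null(guide)) next
      return(list(amplicon = amp, guide = guide))
    }
    stop("could not generate a valid toy amplicon in ", maxTries, " tries")
  })
}

#' Simulation configuration
#'
#' Parameters of the paired-read simulator, mirroring a MiSeq 2x300
#' amplicon run on a Cas9-edited cell population. Defaults encode the
#' emulated study conditions: read pairs covering the full amplicon, indel
#' sizes from a geometric body (most indels 1-3 nt) with a uniform large
#' tail capped at 50 nt, indel positions centred on the predicted cut with
#' discretized normal jitter (sd 4 nt, so >= 90\% of events fall within
#' 10 bp of the cut), uniform substitution sequencing errors, and 36000
#' read pairs. An unedited control is \code{editedFraction = 0} with errors
#' only.
#'
#' @param nReads number of read pairs.
#' @param editedFraction fraction of reads carrying one planted indel; the
#'   edited read count is deterministic (\code{round(nReads * editedFraction)},
#'   then shuffled) unless \code{binomialEdited} is TRUE.
#' @param insertionProb probability a planted indel is an insertion.
#' @param geomSizeProb geometric success parameter of the small-indel body
#'   (size = 1 + Geom(geomSizeProb), capped at maxIndelSize).
#' @param largeTailProb probability of drawing from the uniform large-indel
#'   tail (10..maxIndelSize nt) instead of the geometric body.
#' @param maxIndelSize largest indel size (default 50).
#' @param positionSd sd (nt) of the normal jitter of the event centre
#'   around the cut.
#' @param subErrorRate per-base substitution sequencing-error probability.
#' @param readLength read length (default 300).
#' @param baseQuality constant Phred quality written for every base.
#' @param binomialEdited draw the edited-read count binomially instead of
#'   deterministically (for calibration studies).
#' @param seed integer seed; same seed and config give byte-identical reads
#'   and manifest.
#' @return A named list of validated parameters.
#' @examples
#' simulationConfig(nReads = 1000, editedFraction = 0)
#' @export
simulationConfig <- function(nReads = 36000L, editedFraction = 0.5,
                             insertionProb = 0.3, geomSizeProb = 0.4,
                             largeTailProb = 0.15, maxIndelSize = 50L,
                             positionSd = 4, subErrorRate = 0.001,
                             readLength = 300L, baseQuality = 37L,
                             binomialEdited = FALSE, seed = 1L) {
  cfg <- list(nReads = as.integer(nReads), editedFraction = editedFraction,
              insertionProb = insertionProb, geomSizeProb = geomSizeProb,
              largeTailProb = largeTailProb,
              maxIndelSize = as.integer(maxIndelSize),
              positionSd = positionSd, subErrorRate = subErrorRate,
              readLength = as.integer(readLength),
              baseQuality = as.integer(baseQuality),
              binomialEdited = isTRUE(binomialEdited), seed = as.integer(seed))
  probs <- c(cfg$editedFraction, cfg$insertionProb, cfg$geomSizeProb,
             cfg$largeTailProb, cfg$subErrorRate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$nReads < 1L) stop("nReads must be >= 1")
  if (cfg$maxIndelSize < 1L) stop("maxIndelSize must be >= 1")
  cfg
}

# left-normalize a single planted event against the reference (simulator-side
# R implementation, kept separate from the aligner's C++ normalizer)
.leftNormalizeEvent <- function(refSeq, kind, start, len, alt) {
  if (kind == "deletion") {
    while (start > 1L &&
           substr(refSeq, start - 1L, start - 1L) ==
           substr(refSeq, start + len - 1L, start + len - 1L))
      start <- start - 1L
  } else if (kind == "insertion") {
    while (start > 1L &&
           substr(refSeq, start - 1L, start - 1L) == substr(alt, len, len)) {
      alt <- paste0(substr(refSeq, start - 1L, start - 1L),
                    substr(alt, 1L, len - 1L))
      start <- start - 1L
    }
  }
  list(start = start, alt = alt)
}

#' Simulate an amplicon sequencing sample with ground truth
#'
#' Generates paired 2x300-style reads from an edited cell population:
#' \code{round(nReads * editedFraction)} reads carry exactly one planted
#' indel (size and position drawn per the config, left-normalized against
#' the reference), the rest are unedited; uniform substitution sequencing
#' errors are overlaid on every read; the pair is cut from the (mutant)
#' amplicon as its first and last \code{readLength} bases. Every read gets
#' a truth-manifest row: the planted event and its consequences (coding
#' category, splice changes, premature stop, residue changes, disruptive
#' flag, T7E1 detectability) computed from the planted event by the
#' classification rules, independently of the read-processing pipeline.
#'
#' @param amplicon an \code{\link{Amplicon-class}}.
#' @param guide a \code{\link{GuideTarget-class}} on that amplicon.
#' @param config a \code{\link{simulationConfig}}.
#' @param thresholds an \code{\link{editThresholds}} (for the manifest's
#'   disruptive and T7E1 flags).
#' @return list with \code{reads1}, \code{reads2}
#'   (\code{QualityScaledDNAStringSet}), \code{manifest} (data.frame, one
#'   row per read) and \code{truth} (named list of exact sample-level
#'   fractions computed from the manifest).
#' @examples
#' toy <- makeToyAmplicon(seed = 1)
#' sim <- simulateReads(toy$amplicon, toy$guide,
#'                      simulationConfig(nReads = 100, seed = 5))
#' sim$truth$pctDisruptive
#' @export
simulateReads <- function(amplicon, guide, config = simulationConfig(),
                          thresholds = editThresholds()) {
  stopifnot(is(amplicon, "Amplicon"), is(guide, "GuideTarget"))
  refSeq <- as.character(amplicon@sequence)
  refLen <- nchar(refSeq)
  cut <- guide@cutPos
  n <- config$nReads
  rl <- config$readLength

  .withSeed(config$seed, {
    nEdit <- if (config$binomialEdited) rbinom(1L, n, config$editedFraction)
             else as.integer(round(n * config$editedFraction))
    edited <- sample(rep(c(TRUE, FALSE), c(nEdit, n - nEdit)))

    kind <- rep(NA_character_, n)
    size <- integer(n)
    startPos <- rep(NA_integer_, n)
    altSeq <- rep(NA_character_, n)
    for (i in which(edited)) {
      k <- if (runif(1) < config$insertionProb) "insertion" else "deletion"
      s <- if (runif(1) < config$largeTailProb)
        sample(10:config$maxIndelSize, 1L)
      else min(config$maxIndelSize, 1L + rgeom(1L, config$geomSizeProb))
      centre <- cut + as.integer(round(rnorm(1L, 0, config$positionSd)))
      if (k == "deletion") {
        st <- centre - s %/% 2L
        st <- max(2L, min(st, refLen - s))
        alt <- ""
      } else {
        st <- max(2L, min(centre, refLen))  # insert before position st
        alt <- .randomDNA(s)
      }
      norm <- .leftNormalizeEvent(refSeq, k, st, s, alt)
      kind[i] <- k; size[i] <- s
      startPos[i] <- norm$start; altSeq[i] <- norm$alt
    }

    ids <- sprintf("read_%06d", seq_len(n))
    seq1 <- character(n); seq2 <- character(n)
    for (i in seq_len(n)) {
      mutant <- if (!edited[i]) refSeq
      else if (kind[i] == "deletion")
        paste0(substr(refSeq, 1L, startPos[i] - 1L),
               substr(refSeq, startPos[i] + size[i], refLen))
      else
        paste0(substr(refSeq, 1L, startPos[i] - 1L), altSeq[i],
               substr(refSeq, startPos[i], refLen))
      L <- nchar(mutant)
      seq1[i] <- substr(mutant, 1L, min(rl, L))
      seq2[i] <- as.character(reverseComplement(DNAString(
        substr(mutant, max(1L, L - rl + 1L), L))))
    }

    if (config$subErrorRate > 0) {
      seq1 <- .addSubErrors(seq1, config$subErrorRate)
      seq2 <- .addSubErrors(seq2, config$subErrorRate)
    }

    qual1 <- .intToPhred(lapply(nchar(seq1), function(L)
      rep(config$baseQuality, L)))
    qual2 <- .intToPhred(lapply(nchar(seq2), function(L)
      rep(config$baseQuality, L)))
    reads1 <- .asQSDSS(seq1, qual1, ids)
    reads2 <- .asQSDSS(seq2, qual2, ids)

    manifest <- .buildManifest(ids, edited, kind, size, startPos, altSeq,
                               amplicon, thresholds)
    list(reads1 = reads1, reads2 = reads2, manifest = manifest,
         truth = .manifestTruth(manifest))
  })
}

.addSubErrors <- function(seqs, rate) {
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    L <- nchar(s)
    nerr <- rbinom(1L, L, rate)
    if (nerr == 0L) return(s)
    pos <- sample.int(L, nerr)
    ch <- strsplit(s, "")[[1]]
    for (p in pos) {
      alt <- sample(setdiff(bases, ch[p]), 1L)
      ch[p] <- alt
    }
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

# truth-manifest rows: classification of the planted events by the
# closed-form rules
.buildManifest <- function(ids, edited, kind, size, startPos, altSeq,
                           amplicon, thresholds) {
  n <- length(ids)
  events <- data.frame(readId = ids[edited], kind = kind[edited],
                       start = startPos[edited], length = size[edited],
                       alt = altSeq[edited], stringsAsFactors = FALSE)
  stats <- .perReadEventStats(events, amplicon, ids)
  category <- .codingCategories(events, amplicon, ids)
  premature <- logical(n); residues <- integer(n)
  for (i in which(edited)) {
    ev <- events[events$readId == ids[i], , drop = FALSE]
    if (stats$anyExonEvent[i] || stats$codingIndel[i]) {
      pc <- proteinConsequence(ev, amplicon)
      premature[i] <- pc$prematureStop
      residues[i] <- pc$residueChanges
    }
  }
  out <- data.frame(
    readId = ids, edited = edited, kind = kind,
    size = ifelse(is.na(kind), 0L,
                  ifelse(kind == "insertion", size, -size)),
    start = startPos, alt = altSeq,
    category = category,
    codingIndel = stats$codingIndel,
    splice5Changes = stats$splice5Changes,
    splice3Changes = stats$splice3Changes,
    prematureStop = premature, residueChanges = residues,
    t7e1Detectable = edited & kind != "substitution" &
      size >= thresholds@t7e1MinIndel & !is.na(kind),
    stringsAsFactors = FALSE)
  out$t7e1Detectable[is.na(out$t7e1Detectable)] <- FALSE
  out$disruptive <- isDisruptive(out, thresholds)
  out
}

.manifestTruth <- function(manifest) {
  n <- nrow(manifest)
  nMod <- sum(manifest$edited)
  catOfMod <- manifest$category[manifest$edited]
  pct <- function(k, d) if (d > 0) 100 * k / d else NA_real_
  list(nReads = n, nEdited = nMod,
       pctModified = pct(nMod, n),
       pctFrameshift = pct(sum(catOfMod == "frameshift"), nMod),
       pctInFrame = pct(sum(catOfMod == "in_frame"), nMod),
       pctNoncoding = pct(sum(catOfMod == "noncoding"), nMod),
       pctSplice5Modified = pct(sum(manifest$splice5Changes > 0L), n),
       pctSplice5Disrupted = pct(sum(manifest$splice5Changes > 1L), n),
       pctSplice3Modified = pct(sum(manifest$splice3Changes > 0L), n),
       pctDisruptive = pct(sum(manifest$disruptive), n),
       pctFrameshiftOfAll = pct(sum(manifest$category == "frameshift"), n),
       pctT7E1 = pct(sum(manifest$t7e1Detectable), n))
}
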