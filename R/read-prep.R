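#' @include AllClasses.R
NULL

.asQSDSS <- function(seqs, quals, ids) {
  x <- QualityScaledDNAStringSet(DNAStringSet(seqs), PhredQuality(quals))
  names(x) <- ids
  x
}

#' Trim adapters and low-quality 3' tails
#'
#' Per read: the best 3' adapter match (at most 10\% mismatches over at
#' least 3 aligned bases; "best" maximises matching bases) and everything
#' after it are removed; then the 3' end is trimmed by the standard
#' running-sum quality algorithm, cutting at the leftmost minimum of the
#' 3'-anchored partial sums of \code{q - qualCutoff}. Reads are never
#' lengthened; a read may become empty (dropped later by the merge step).
#'
#' @param reads \code{QualityScaledDNAStringSet} (Phred+33 qualities).
#' @param adapter adapter sequence to remove, or NULL to skip adapter
#'   trimming.
#' @param qualCutoff Phred cutoff for quality trimming (default 20).
#' @return A trimmed \code{QualityScaledDNAStringSet} (same names/order).
#' @examples
#' r <- QualityScaledDNAStringSet(Biostrings::DNAStringSet("ACGTACGT"),
#'        Biostrings::PhredQuality("IIIII###"))
#' names(r) <- "r1"
#' trimReads(r, qualCutoff = 20)
#' @export
trimReads <- function(reads, adapter = NULL, qualCutoff = 20L) {
  stopifnot(is(reads, "QualityScaledDNAStringSet"))
  if (qualCutoff < 0L) stop("qualCutoff must be >= 0")
  if (!is.null(adapter)) {
    adapter <- toupper(adapter)
    if (nchar(adapter) == 0L) stop("adapter must be non-empty or NULL")
  }
  seqs <- as.character(reads)
  quals <- as.character(quality(reads))
  keep <- cpp_trim_lengths(seqs, quals,
                           if (is.null(adapter)) "" else adapter,
                           as.integer(qualCutoff))
  .asQSDSS(substr(seqs, 1L, keep), substr(quals, 1L, keep), names(reads))
}

#' Merge overlapping read pairs into contiguous amplicon reads
#'
#' Reverse-complements each reverse mate and scores every relative placement
#' with at least \code{minOverlap} overlapping bases; the placement with the
#' smallest overlap mismatch fraction wins (ties: longer overlap, then
#' smaller offset). The pair is merged when that fraction is at most
#' \code{maxMismatchFrac}; disagreeing overlap bases take the higher-quality
#' call (the forward base on ties). Pairs that fail to merge are a normal
#' outcome, recorded in the info table and excluded from mutation analysis
#' (only contiguous amplicon-spanning reads are classified).
#'
#' @param reads1 forward reads (\code{QualityScaledDNAStringSet}).
#' @param reads2 reverse-strand mates, same length and order.
#' @param minOverlap minimum overlap length (default 10).
#' @param maxMismatchFrac maximum overlap mismatch fraction (default 0.25).
#' @return list with \code{reads}: merged \code{QualityScaledDNAStringSet}
#'   (merged pairs only), and \code{info}: data.frame(readId, merged,
#'   overlap, mismatches, offset).
#' @examples
#' toy <- makeToyAmplicon(seed = 1)
#' sim <- simulateReads(toy$amplicon, toy$guide,
#'                      simulationConfig(nReads = 10, seed = 7))
#' mergePairs(sim$reads1, sim$reads2)$info[1:3, ]
#' @export
mergePairs <- function(reads1, reads2, minOverlap = 10L,
                       maxMismatchFrac = 0.25) {
  stopifnot(is(reads1, "QualityScaledDNAStringSet"),
            is(reads2, "QualityScaledDNAStringSet"))
  if (length(reads1) != length(reads2))
    stop("reads1 and reads2 must have the same length")
  if (minOverlap < 1L) stop("minOverlap must be >= 1")
  res <- cpp_merge_pairs(as.character(reads1), as.character(quality(reads1)),
                         as.character(reads2), as.character(quality(reads2)),
                         as.integer(minOverlap), maxMismatchFrac)
  ids <- names(reads1)
  if (is.null(ids)) ids <- as.character(seq_along(reads1))
  ok <- res$merged
  merged <- .asQSDSS(res$seq[ok], res$qual[ok], ids[ok])
  info <- data.frame(readId = ids, merged = res$merged,
                     overlap = res$overlap, mismatches = res$mismatches,
                     offset = res$offset, stringsAsFactors = FALSE)
  list(reads = merged, info = info)
}
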