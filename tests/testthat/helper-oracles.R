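# Independent oracles used across the suite. These deliberately re-derive
# results through different formulations than the package (row-vectorized
# dynamic program for alignment scores, direct string surgery for mutant
# reconstruction, Biostrings translation) so agreement is informative.

randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

phred <- function(q, n) paste(rep(intToUtf8(q + 33L), n), collapse = "")

intToPhredTest <- function(v) intToUtf8(v + 33L, multiple = FALSE)

qsdss <- function(seqs, quals, ids = sprintf("r%d", seq_along(seqs))) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
  names(x) <- ids
  x
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Slow affine-gap semi-global DP, score only. Free reference end gaps, full
# query aligned; a gap of length L costs gapOpen + L * gapExtend. The
# reference-gap (query-insertion consuming) matrix is computed column-wise
# from the previous row; the deletion matrix via a running-max recentred by
# the gap-extension slope, so the formulation differs from a cellwise
# three-matrix traceback DP.
alignScoreOracle <- function(query, ref, match = 2, mismatch = -4,
                             gapOpen = -12, gapExtend = -1) {
  m <- nchar(query); n <- nchar(ref)
  qc <- strsplit(query, "")[[1]]
  rc <- strsplit(ref, "")[[1]]
  NEG <- -1e9
  Mp <- rep(0, n + 1)
  Ip <- rep(NEG, n + 1)
  Dp <- rep(NEG, n + 1)
  for (i in seq_len(m)) {
    sub <- ifelse(rc == qc[i], match, mismatch)
    Sprev <- pmax(Mp, Ip, Dp)
    Mc <- c(NEG, Sprev[1:n] + sub)
    Ic <- pmax(Mp + gapOpen + gapExtend, Ip + gapExtend,
               Dp + gapOpen + gapExtend)
    val <- pmax(Mc, Ic) - gapExtend * (0:n)
    cm <- cummax(val)
    Dc <- c(NEG, gapOpen + gapExtend * (1:n) + cm[1:n])
    Mp <- Mc; Ip <- Ic; Dp <- Dc
  }
  max(pmax(Mp, Ip, Dp))
}

# apply an events table to a reference by direct string surgery (right to
# left so earlier coordinates stay valid); independent of the package's
# internal reconstruction
applyEventsOracle <- function(refSeq, events) {
  if (nrow(events) == 0L) return(refSeq)
  events <- events[order(-events$start), , drop = FALSE]
  s <- refSeq
  for (i in seq_len(nrow(events))) {
    st <- events$start[i]; L <- events$length[i]
    s <- switch(events$kind[i],
      deletion = paste0(substr(s, 1, st - 1), substr(s, st + L, nchar(s))),
      insertion = paste0(substr(s, 1, st - 1), events$alt[i],
                         substr(s, st, nchar(s))),
      substitution = paste0(substr(s, 1, st - 1), events$alt[i],
                            substr(s, st + L, nchar(s))))
  }
  s
}

translateOracle <- function(seq) {
  nc <- 3L * (nchar(seq) %/% 3L)
  if (nc == 0L) return("")
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1, nc)))))
}

# closed-form coding-category rule for a single indel: exon overlap times
# length-mod-3 (insertions by strict junction interiority)
singleIndelCategoryOracle <- function(kind, start, len, exonStart, exonEnd) {
  if (kind == "insertion") {
    inside <- start > exonStart && start <= exonEnd
    if (!inside) return("noncoding")
    if (len %% 3 == 0) "in_frame" else "frameshift"
  } else {
    ov <- max(0, min(start + len - 1, exonEnd) - max(start, exonStart) + 1)
    if (ov == 0) return("noncoding")
    if (ov %% 3 == 0) "in_frame" else "frameshift"
  }
}

toyFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makeToyAmplicon(seed = 1)
    cache
  }
})
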