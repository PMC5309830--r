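#' @include AllClasses.R
NULL

#' Locate a protospacer (with PAM) on an amplicon
#'
#' Scans both strands of the amplicon for the 20-nt protospacer immediately
#' followed by the PAM (default NGG, SpCas9) and returns the unique hit as a
#' \code{\link{GuideTarget-class}}. The predicted blunt cut lies between the
#' 17th and 18th protospacer base, 3 bp 5' of the PAM, on the protospacer's
#' strand; \code{cutSite} reports it projected to amplicon coordinates as the
#' position immediately left of the cut.
#'
#' @param amplicon an \code{\link{Amplicon-class}}.
#' @param protospacer 20-nt character string over A/C/G/T (5'->3' on its
#'   strand).
#' @param pam PAM pattern; IUPAC codes allowed (default "NGG").
#' @return A \code{GuideTarget}. Zero hits raise a not-found error; several
#'   hits raise an ambiguity error listing all positions.
#' @examples
#' toy <- makeToyAmplicon(seed = 1)
#' locateGuide(toy$amplicon, protospacerSeq(toy$guide))
#' @export
locateGuide <- function(amplicon, protospacer, pam = "NGG") {
  stopifnot(is(amplicon, "Amplicon"))
  protospacer <- toupper(protospacer)
  if (nchar(protospacer) != 20L || grepl("[^ACGT]", protospacer))
    stop("protospacer must be a 20-nt string over A/C/G/T")
  seq <- amplicon@sequence
  plen <- nchar(protospacer)
  pamlen <- nchar(pam)

  fwdPat <- DNAString(paste0(protospacer, pam))
  fwd <- matchPattern(fwdPat, seq, fixed = FALSE)
  revPat <- reverseComplement(fwdPat)
  rev <- matchPattern(revPat, seq, fixed = FALSE)

  hits <- data.frame(
    strand = c(rep("+", length(fwd)), rep("-", length(rev))),
    protoStart = c(start(fwd), start(rev) + pamlen),
    pamStart = c(start(fwd) + plen, start(rev)))
  if (nrow(hits) == 0L)
    stop("protospacer ", protospacer, " (PAM ", pam,
         ") not found on either strand of amplicon \"", amplicon@id, "\"")
  if (nrow(hits) > 1L)
    stop("protospacer ", protospacer, " is ambiguous on amplicon \"",
         amplicon@id, "\": hits at ",
         paste0(hits$strand, hits$protoStart, collapse = ", "))

  st <- hits$strand[1]
  ps <- hits$protoStart[1]
  # blunt cut between protospacer bases 17|18 (3 bp 5' of the PAM)
  cut <- if (st == "+") ps + plen - 4L else ps + 2L
  pamSeq <- if (st == "+") {
    as.character(seq[IRanges(hits$pamStart[1], width = pamlen)])
  } else {
    as.character(reverseComplement(seq[IRanges(hits$pamStart[1], width = pamlen)]))
  }
  new("GuideTarget", protospacer = protospacer, strand = st,
      start = as.integer(ps), pam = pamSeq, cutPos = as.integer(cut))
}
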