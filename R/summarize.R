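#' @include classify.R
NULL

#' Wilson score interval for a binomial proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return data.frame(proportion, lower, upper); well-behaved near 0 and 1.
#' @examples
#' wilsonInterval(40, 100)
#' @export
wilsonInterval <- function(k, n, conf = 0.95) {
  stopifnot(all(k >= 0), all(n > 0), all(k <= n))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  data.frame(proportion = p, lower = pmax(0, centre - half),
             upper = pmin(1, centre + half))
}

#' Two-proportion z-test (pooled, no continuity correction)
#'
#' @param k1,n1,k2,n2 successes and trials of the two groups.
#' @return list(z, pValue) with the two-sided p-value.
#' @examples
#' twoProportionTest(2500, 5000, 1500, 5000)
#' @export
twoProportionTest <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, pValue = 2 * pnorm(-abs(z)))
}

#' Summarize per-read outcomes into a per-sample report
#'
#' Computes the numeric per-sample editing report: the modified fraction of
#' filter-passing reads; the frameshift / in-frame / noncoding split of
#' modified reads (unmodified reads are excluded from that denominator); 5'
#' and 3' splice-window modification rates and the disruptive fraction, both
#' over filter-passing reads; the signed indel-size histogram; the
#' per-position event profile; and, when a guide is given, the fraction of
#' indel events within the near-target window of the predicted cut. All
#' denominators are carried in the object. With zero filter-passing reads
#' an explicitly empty summary is returned (no division by zero).
#'
#' @param outcomes per-read outcome table from \code{\link{classifyReads}}.
#' @param events event table from \code{\link{alignmentEvents}}.
#' @param amplicon the \code{\link{Amplicon-class}}.
#' @param guide optional \code{\link{GuideTarget-class}} for cut-proximity.
#' @param thresholds an \code{\link{editThresholds}} object.
#' @param sampleId,lineage,passage sample metadata; \code{lineage} defaults
#'   to \code{sampleId}, \code{passage} to NA.
#' @param nTotal,nMerged read-accounting denominators (default: rows of
#'   \code{outcomes}, i.e. when trimming/merging QC is tracked upstream pass
#'   the true counts).
#' @return A \code{\link{SampleSummary-class}} object.
#' @examples
#' toy <- makeToyAmplicon(seed = 1)
#' sim <- simulateReads(toy$amplicon, toy$guide,
#'                      simulationConfig(nReads = 50, subErrorRate = 0, seed = 2))
#' m <- mergePairs(sim$reads1, sim$reads2)
#' aln <- alignReads(m$reads, toy$amplicon)
#' out <- classifyReads(aln, toy$amplicon)
#' summarizeSample(out, alignmentEvents(aln), toy$amplicon, toy$guide,
#'                 sampleId = "demo")
#' @export
summarizeSample <- function(outcomes, events, amplicon, guide = NULL,
                            thresholds = editThresholds(),
                            sampleId = "sample", lineage = sampleId,
                            passage = NA_integer_,
                            nTotal = nrow(outcomes), nMerged = nrow(outcomes)) {
  stopifnot(is(amplicon, "Amplicon"), is(thresholds, "EditThresholds"))
  .checkEvents(events)
  keep <- outcomes$passesFilter
  po <- outcomes[keep, , drop = FALSE]
  pe <- events[events$readId %in% po$readId, , drop = FALSE]
  nPass <- nrow(po)
  pct <- function(k, n) if (n > 0L) 100 * k / n else NA_real_

  nMod <- sum(po$modified)
  nDis <- sum(po$disruptive)
  catOfMod <- po$category[po$modified]
  nearCut <- if (!is.null(guide))
    100 * nearCutFraction(pe, guide, thresholds@nearTargetWindow)
  else NaN
  if (is.nan(nearCut)) nearCut <- NA_real_

  new("SampleSummary",
      sampleId = sampleId, lineage = lineage, passage = as.integer(passage),
      nTotal = as.integer(nTotal), nMerged = as.integer(nMerged),
      nPassFilter = as.integer(nPass), nModified = as.integer(nMod),
      nDisruptive = as.integer(nDis),
      pctModified = pct(nMod, nPass),
      pctFrameshift = pct(sum(catOfMod == "frameshift"), nMod),
      pctInFrame = pct(sum(catOfMod == "in_frame"), nMod),
      pctNoncoding = pct(sum(catOfMod == "noncoding"), nMod),
      pctSplice5Modified = pct(sum(po$splice5Changes > 0L), nPass),
      pctSplice3Modified = pct(sum(po$splice3Changes > 0L), nPass),
      pctDisruptive = pct(nDis, nPass),
      pctEventsNearCut = nearCut,
      indelHistogram = indelSizeDistribution(pe, po$readId),
      positionalProfile = positionalProfile(pe, amplicon),
      isEmpty = nPass == 0L)
}

#' Compare the disruptive fraction across passages
#'
#' Tests whether the disruptive-mutation fraction of one cell lineage is
#' stable across serial passages: per-passage Wilson 95\% intervals, all
#' pairwise pooled two-proportion z-tests, and a single stability call. The
#' pairwise p-values are Holm-adjusted so the family-wise type-I error of
#' the stability call is approximately \code{alpha}; the lineage is declared
#' stable when no adjusted p-value falls below \code{alpha}.
#'
#' @param summaries list of \code{\link{SampleSummary-class}} objects from
#'   one lineage (at least 2), or a data.frame with columns \code{passage},
#'   \code{k} (disruptive reads) and \code{n} (filter-passing reads).
#' @param alpha family-wise significance level (default 0.05).
#' @param conf confidence level of the per-passage intervals (default 0.95).
#' @return A \code{\link{StabilityReport-class}} object.
#' @examples
#' comparePassages(data.frame(passage = c(2, 3, 5), k = c(410, 395, 402),
#'                            n = c(1000, 1000, 1000)))
#' @export
comparePassages <- function(summaries, alpha = 0.05, conf = 0.95) {
  if (is.data.frame(summaries)) {
    df <- summaries
    stopifnot(all(c("passage", "k", "n") %in% names(df)))
    lineage <- if ("lineage" %in% names(df)) unique(df$lineage) else "lineage"
  } else {
    stopifnot(all(vapply(summaries, is, TRUE, "SampleSummary")))
    lineage <- unique(vapply(summaries, function(s) s@lineage, ""))
    df <- do.call(rbind, lapply(summaries, function(s)
      data.frame(passage = s@passage, k = s@nDisruptive, n = s@nPassFilter)))
  }
  if (length(lineage) != 1L)
    stop("summaries come from different lineages: ",
         paste(lineage, collapse = ", "))
  if (nrow(df) < 2L) stop("need at least two passages to compare")
  df <- df[order(df$passage), , drop = FALSE]

  ci <- wilsonInterval(df$k, df$n, conf = conf)
  perPassage <- data.frame(passage = df$passage, k = df$k, n = df$n, ci)

  pairs <- utils::combn(nrow(df), 2L)
  pw <- do.call(rbind, apply(pairs, 2L, function(idx) {
    a <- idx[1]; b <- idx[2]
    t <- twoProportionTest(df$k[a], df$n[a], df$k[b], df$n[b])
    data.frame(passage1 = df$passage[a], passage2 = df$passage[b],
               z = t$z, pValue = t$pValue)
  }))
  pw$pAdjusted <- stats::p.adjust(pw$pValue, method = "holm")

  new("StabilityReport", lineage = lineage, alpha = alpha,
      perPassage = perPassage, pairwise = pw,
      maxAbsDiff = {p <- df$k / df$n; max(abs(outer(p, p, "-")))},
      stable = all(pw$pAdjusted >= alpha))
}
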