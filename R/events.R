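#' @include AllClasses.R
NULL

.checkEvents <- function(events) {
  need <- c("readId", "kind", "start", "length", "alt")
  if (!all(need %in% names(events)))
    stop("events table must have columns ", paste(need, collapse = ", "))
  if (nrow(events) && !all(events$kind %in% .EVENT_KINDS))
    stop("unknown event kind(s): ",
         paste(setdiff(unique(events$kind), .EVENT_KINDS), collapse = ", "))
  invisible(events)
}

# signed indel size: insertions positive, deletions negative, subs NA
.signedSize <- function(events) {
  ifelse(events$kind == "insertion", events$length,
         ifelse(events$kind == "deletion", -events$length, NA_integer_))
}

# per-event overlap (nt) with a closed interval [lo, hi]; insertions count
# their inserted length when the junction is strictly inside the interval
# (inserted bases fall between reference positions start-1 and start)
.eventIntervalOverlap <- function(events, lo, hi) {
  ov <- integer(nrow(events))
  ind <- events$kind != "insertion"
  ov[ind] <- pmax(0L, pmin(events$start[ind] + events$length[ind] - 1L, hi) -
                       pmax(events$start[ind], lo) + 1L)
  ins <- !ind
  inside <- ins & events$start > lo & events$start <= hi
  ov[inside] <- events$length[inside]
  ov
}

#' Signed indel-size distribution
#'
#' Counts indel events per signed size (insertions positive, deletions
#' negative) over a set of reads, with a 0 bin counting the reads that carry
#' no indel at all (unmodified or substitution-only).
#'
#' @param events event table (see \code{\link{alignmentEvents}}), already
#'   restricted to the reads of interest (typically filter-passing reads).
#' @param readIds ids of all reads considered; reads absent from
#'   \code{events}' indels contribute to the 0 bin.
#' @return data.frame(size, count) sorted by size.
#' @examples
#' ev <- data.frame(readId = c("a", "b"), kind = c("deletion", "insertion"),
#'                  start = c(10L, 20L), length = c(3L, 1L),
#'                  alt = c("", "T"))
#' indelSizeDistribution(ev, readIds = c("a", "b", "c"))
#' @export
indelSizeDistribution <- function(events, readIds) {
  .checkEvents(events)
  sz <- .signedSize(events)
  indel <- !is.na(sz)
  zero <- sum(!readIds %in% events$readId[indel])
  tab <- table(sz[indel])
  df <- data.frame(size = c(as.integer(names(tab)), 0L),
                   count = c(as.integer(tab), zero))
  df <- aggregate(count ~ size, df, sum)
  df <- df[order(df$size), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Per-position event profile along the amplicon
#'
#' For every reference position, how many reads carry a deletion covering
#' it, a substitution covering it, or an insertion at that junction
#' (insertions are counted at the position before which the bases are
#' inserted).
#'
#' @param events event table restricted to the reads of interest.
#' @param amplicon the \code{\link{Amplicon-class}}.
#' @return data.frame(position, insertion, deletion, substitution).
#' @examples
#' toy <- makeToyAmplicon(seed = 1)
#' ev <- data.frame(readId = "a", kind = "deletion", start = 150L,
#'                  length = 3L, alt = "")
#' positionalProfile(ev, toy$amplicon)[148:153, ]
#' @export
positionalProfile <- function(events, amplicon) {
  stopifnot(is(amplicon, "Amplicon"))
  .checkEvents(events)
  n <- length(amplicon@sequence)
  prof <- matrix(0L, nrow = n, ncol = 3L,
                 dimnames = list(NULL, c("insertion", "deletion",
                                         "substitution")))
  for (k in c("deletion", "substitution")) {
    ev <- events[events$kind == k, , drop = FALSE]
    if (nrow(ev)) {
      pos <- sequence(ev$length, from = ev$start)
      pos <- pos[pos >= 1L & pos <= n]
      t <- tabulate(pos, nbins = n)
      prof[, k] <- prof[, k] + t
    }
  }
  ins <- events[events$kind == "insertion", , drop = FALSE]
  if (nrow(ins)) {
    pos <- ins$start[ins$start >= 1L & ins$start <= n]
    prof[, "insertion"] <- tabulate(pos, nbins = n)
  }
  data.frame(position = seq_len(n), prof)
}

#' Distance of indel events to a predicted cut site
#'
#' \code{eventCutDistance} returns, per indel event, the distance from the
#' predicted cut to the event's nearest edge (0 when the event covers the
#' cut). \code{nearCutFraction} is the fraction of indel events within
#' \code{window} bp of the cut.
#'
#' @param events event table; substitution rows are ignored.
#' @param guide a \code{\link{GuideTarget-class}} (its \code{cutSite} is
#'   used).
#' @param window distance threshold in bp (default 10).
#' @return \code{eventCutDistance}: integer vector (one per indel event);
#'   \code{nearCutFraction}: a single fraction in [0, 1] (NaN if there are
#'   no indel events).
#' @export
eventCutDistance <- function(events, guide) {
  stopifnot(is(guide, "GuideTarget"))
  .checkEvents(events)
  ev <- events[events$kind != "substitution", , drop = FALSE]
  cut <- guide@cutPos
  # junction coordinates: junction i sits between bases i and i+1; the cut
  # is junction `cut`, an insertion at `start` is junction start-1, and a
  # deletion of bases [start, start+length-1] spans junctions
  # [start-1, start+length-1]
  lo <- ev$start - 1L
  hi <- ifelse(ev$kind == "insertion", ev$start - 1L,
               ev$start + ev$length - 1L)
  pmax(0L, pmax(lo - cut, cut - hi))
}

#' @rdname eventCutDistance
#' @export
nearCutFraction <- function(events, guide, window = 10L) {
  d <- eventCutDistance(events, guide)
  if (length(d) == 0L) return(NaN)
  mean(d <= window)
}
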