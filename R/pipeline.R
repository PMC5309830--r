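#' @include summarize.R simulate.R
NULL

#' Analyze one sample: reads to per-read outcomes and summary
#'
#' Chains the per-sample stages: adapter/quality trimming of both mates,
#' merging of overlapping pairs (unmerged pairs are excluded from mutation
#' analysis), alignment of merged reads to the amplicon, event extraction,
#' per-read classification, and summarization.
#'
#' @param reads1,reads2 forward and reverse mates
#'   (\code{QualityScaledDNAStringSet}); \code{reads2 = NULL} treats
#'   \code{reads1} as already-merged single reads.
#' @param amplicon the \code{\link{Amplicon-class}}.
#' @param guide optional \code{\link{GuideTarget-class}}.
#' @param sampleId,lineage,passage sample metadata.
#' @param adapter,qualCutoff trimming parameters (see
#'   \code{\link{trimReads}}).
#' @param minOverlap,maxMismatchFrac merging parameters (see
#'   \code{\link{mergePairs}}).
#' @param scoring an \code{\link{alignScoring}}.
#' @param thresholds an \code{\link{editThresholds}}.
#' @return list with \code{summary} (\code{\link{SampleSummary-class}}),
#'   \code{outcomes}, \code{events}, \code{alignments}, and \code{qc}
#'   (one-row data.frame: reads in, trimmed out, merged, unmerged).
#' @examples
#' toy <- makeToyAmplicon(seed = 1)
#' sim <- simulateReads(toy$amplicon, toy$guide,
#'                      simulationConfig(nReads = 40, seed = 11))
#' res <- analyzeSample(sim$reads1, sim$reads2, toy$amplicon, toy$guide,
#'                      sampleId = "demo")
#' res$summary
#' @export
analyzeSample <- function(reads1, reads2 = NULL, amplicon, guide = NULL,
                          sampleId = "sample", lineage = sampleId,
                          passage = NA_integer_,
                          adapter = NULL, qualCutoff = 20L,
                          minOverlap = 10L, maxMismatchFrac = 0.25,
                          scoring = alignScoring(),
                          thresholds = editThresholds()) {
  nTotal <- length(reads1)
  if (!is.null(reads2)) {
    t1 <- trimReads(reads1, adapter, qualCutoff)
    t2 <- trimReads(reads2, adapter, qualCutoff)
    mg <- mergePairs(t1, t2, minOverlap, maxMismatchFrac)
    merged <- mg$reads
    nMerged <- length(merged)
  } else {
    merged <- trimReads(reads1, adapter, qualCutoff)
    merged <- merged[width(merged) > 0L]
    nMerged <- length(merged)
    mg <- list(info = data.frame())
  }
  if (nMerged == 0L) {
    aln <- alignReads(character(0), amplicon, scoring)
  } else {
    aln <- alignReads(merged, amplicon, scoring)
  }
  outcomes <- classifyReads(aln, amplicon, thresholds)
  summary <- summarizeSample(outcomes, aln@events, amplicon, guide,
                             thresholds, sampleId = sampleId,
                             lineage = lineage, passage = passage,
                             nTotal = nTotal, nMerged = nMerged)
  qc <- data.frame(sampleId = sampleId, nTotal = nTotal, nMerged = nMerged,
                   nUnmerged = nTotal - nMerged,
                   nPassFilter = summary@nPassFilter,
                   stringsAsFactors = FALSE)
  list(summary = summary, outcomes = outcomes, events = aln@events,
       alignments = aln, qc = qc)
}

.cfgGet <- function(cfg, key, default = NULL) {
  if (is.null(cfg[[key]])) default else cfg[[key]]
}

#' Run the full pipeline from a config file
#'
#' One entry point chaining simulation (or FASTQ input), per-sample
#' analysis, and cross-passage comparison, with reproducible outputs
#' written to an output directory. The YAML config has keys:
#' \describe{
#'   \item{seed}{integer; all simulation randomness derives from it.}
#'   \item{output_dir}{where result tables are written.}
#'   \item{amplicon}{either \code{toy: \{seed, ...\}} for
#'     \code{\link{makeToyAmplicon}}, or \code{fasta} + annotation keys for
#'     \code{\link{ampliconFromConfig}}.}
#'   \item{samples}{list of \code{\{id, lineage, passage\}} entries, each
#'     with either \code{fastq1}/\code{fastq2} paths or a \code{simulate}
#'     block of \code{\link{simulationConfig}} arguments (snake_case).}
#'   \item{parameters}{optional trim/merge/scoring/threshold overrides.}
#'   \item{alpha}{significance level for the stability comparison.}
#' }
#' Outputs per sample: \code{<id>_outcomes.tsv}, \code{<id>_events.tsv};
#' overall: \code{qc.tsv}, \code{summary.tsv}, \code{stability_<lineage>.tsv}
#' (for lineages with >= 2 passages), and \code{run_info.json} (config
#' hash, seed, package version). Reruns with the same config and seed give
#' byte-identical tables.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#' @param mode which stages to run: "all", "simulate" (write simulated
#'   FASTQ + manifests only), "analyze" (no passage comparison), or
#'   "compare".
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with \code{summaries}, \code{stability} (list
#'   of \code{\link{StabilityReport-class}} per lineage), and the output
#'   directory.
#' @export
runPipeline <- function(config, mode = c("all", "simulate", "analyze",
                                         "compare"), quiet = FALSE) {
  mode <- match.arg(mode)
  cfgPath <- NULL
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfgPath <- config
    cfg <- yaml::read_yaml(config)
  } else cfg <- config
  say <- function(...) if (!quiet) message(...)

  seed <- as.integer(.cfgGet(cfg, "seed", 1L))
  outDir <- .cfgGet(cfg, "output_dir")
  if (is.null(outDir)) stop("config key 'output_dir' is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  ampCfg <- cfg$amplicon
  if (is.null(ampCfg)) stop("config key 'amplicon' is required")
  if (!is.null(ampCfg$toy)) {
    toyArgs <- ampCfg$toy
    toy <- do.call(makeToyAmplicon, c(
      list(seed = as.integer(.cfgGet(toyArgs, "seed", seed)))))
    amplicon <- toy$amplicon
    guides <- list(toy$guide)
    thresholds <- editThresholds()
  } else {
    built <- ampliconFromConfig(ampCfg)
    amplicon <- built$amplicon
    guides <- built$guides
    thresholds <- built$thresholds
  }
  guide <- if (length(guides)) guides[[1]] else NULL

  par <- .cfgGet(cfg, "parameters", list())
  trimPar <- .cfgGet(par, "trim", list())
  mergePar <- .cfgGet(par, "merge", list())
  scorPar <- .cfgGet(par, "scoring", list())
  scoring <- alignScoring(
    match = .cfgGet(scorPar, "match", 2L),
    mismatch = .cfgGet(scorPar, "mismatch", -4L),
    gapOpen = .cfgGet(scorPar, "gap_open", -12L),
    gapExtend = .cfgGet(scorPar, "gap_extend", -1L))

  samples <- cfg$samples
  if (is.null(samples) || !length(samples))
    stop("config key 'samples' is required")

  summaries <- list()
  qcAll <- list()
  for (si in seq_along(samples)) {
    sm <- samples[[si]]
    id <- .cfgGet(sm, "id", paste0("sample", si))
    lineage <- .cfgGet(sm, "lineage", id)
    passage <- .cfgGet(sm, "passage", NA_integer_)
    if (!is.null(sm$simulate)) {
      sb <- sm$simulate
      scfg <- simulationConfig(
        nReads = .cfgGet(sb, "n_reads", 36000L),
        editedFraction = .cfgGet(sb, "edited_fraction", 0.5),
        subErrorRate = .cfgGet(sb, "sub_error_rate", 0.001),
        readLength = .cfgGet(sb, "read_length", 300L),
        seed = seed + si)
      say("simulating sample ", id, " (", scfg$nReads, " read pairs)")
      sim <- simulateReads(amplicon, guide, scfg, thresholds)
      write.table(sim$manifest,
                  file.path(outDir, paste0(id, "_manifest.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (mode == "simulate") {
        writeFastq(sim$reads1, file.path(outDir, paste0(id, "_R1.fastq.gz")))
        writeFastq(sim$reads2, file.path(outDir, paste0(id, "_R2.fastq.gz")))
        next
      }
      r1 <- sim$reads1; r2 <- sim$reads2
    } else {
      if (is.null(sm$fastq1))
        stop("sample '", id, "': config key 'fastq1' (or 'simulate') required")
      if (!file.exists(sm$fastq1))
        stop("sample '", id, "': fastq1 not found: ", sm$fastq1)
      r1 <- readFastq(sm$fastq1)
      r2 <- if (!is.null(sm$fastq2)) readFastq(sm$fastq2) else NULL
      if (mode == "simulate") next
    }
    say("analyzing sample ", id)
    res <- analyzeSample(r1, r2, amplicon, guide, sampleId = id,
                         lineage = lineage, passage = passage,
                         adapter = .cfgGet(trimPar, "adapter"),
                         qualCutoff = .cfgGet(trimPar, "qual_cutoff", 20L),
                         minOverlap = .cfgGet(mergePar, "min_overlap", 10L),
                         maxMismatchFrac = .cfgGet(mergePar,
                                                   "max_mismatch_frac", 0.25),
                         scoring = scoring, thresholds = thresholds)
    write.table(res$outcomes, file.path(outDir, paste0(id, "_outcomes.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$events, file.path(outDir, paste0(id, "_events.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summaries[[id]] <- res$summary
    qcAll[[id]] <- res$qc
  }

  stability <- list()
  if (mode != "simulate" && length(summaries)) {
    write.table(do.call(rbind, lapply(summaries, summaryRow)),
                file.path(outDir, "summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(do.call(rbind, qcAll), file.path(outDir, "qc.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (mode %in% c("all", "compare")) {
      lineages <- vapply(summaries, function(s) s@lineage, "")
      for (lin in unique(lineages)) {
        grp <- summaries[lineages == lin]
        if (length(grp) >= 2L) {
          rep <- comparePassages(grp, alpha = .cfgGet(cfg, "alpha", 0.05))
          stability[[lin]] <- rep
          write.table(cbind(lineage = lin, rep@perPassage),
                      file.path(outDir, paste0("stability_", lin, ".tsv")),
                      sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    }
  }

  info <- list(package = "indelScope",
               version = as.character(utils::packageVersion("indelScope")),
               seed = seed, mode = mode,
               configHash = .configHash(cfg),
               configFile = if (is.null(cfgPath)) NA else cfgPath)
  jsonlite::write_json(info, file.path(outDir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(summaries = summaries, stability = stability,
                 outputDir = outDir))
}

.configHash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(cfg), f)
  unname(tools::md5sum(f))
}
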