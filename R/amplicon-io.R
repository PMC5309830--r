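#' @include AllClasses.R
NULL

#' Build an Amplicon (plus guides and thresholds) from a config
#'
#' Reads the reference sequence from a FASTA file and the annotation from a
#' YAML config (or an equivalent R list) with keys \code{exon},
#' \code{intron5}, \code{intron3}, \code{splice5}, \code{splice3} (each a
#' 1-based \code{[start, end]} pair), \code{frame_offset}, optional
#' \code{guides} (character protospacers) and optional \code{thresholds}
#' (names matching the \code{\link{editThresholds}} arguments in snake_case).
#'
#' @param config path to a YAML file or a named list.
#' @param fasta path to the reference FASTA (single record); may be omitted
#'   when the config carries a \code{fasta} key or a literal \code{sequence}.
#' @return list with elements \code{amplicon}, \code{guides} (list of
#'   \code{GuideTarget}, possibly empty) and \code{thresholds}.
#' @export
ampliconFromConfig <- function(config, fasta = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(fasta)) fasta <- cfg$fasta
  if (!is.null(fasta)) {
    if (!file.exists(fasta)) stop("reference FASTA not found: ", fasta)
    ss <- readDNAStringSet(fasta)
    if (length(ss) != 1L) stop("reference FASTA must contain one record")
    seq <- as.character(ss[[1]])
    id <- names(ss)[1]
  } else if (!is.null(cfg$sequence)) {
    seq <- cfg$sequence
    id <- if (is.null(cfg$id)) "amplicon" else cfg$id
  } else stop("config must provide 'fasta' or 'sequence'")

  need <- c("exon", "intron5", "intron3", "splice5", "splice3")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("amplicon config missing key(s): ", paste(miss, collapse = ", "))
  fo <- if (is.null(cfg$frame_offset)) 0L else as.integer(cfg$frame_offset)
  amp <- Amplicon(seq, exon = unlist(cfg$exon),
                  intron5 = unlist(cfg$intron5), intron3 = unlist(cfg$intron3),
                  splice5 = unlist(cfg$splice5), splice3 = unlist(cfg$splice3),
                  id = id, frameOffset = fo)
  guides <- lapply(cfg$guides, function(g) locateGuide(amp, g))
  th <- cfg$thresholds
  thresholds <- editThresholds(
    spliceChangeMax = if (is.null(th$splice_change_max)) 1L else th$splice_change_max,
    residueChangeMax = if (is.null(th$residue_change_max)) 5L else th$residue_change_max,
    minDisruptiveIndelResidues =
      if (is.null(th$min_disruptive_indel_residues)) 5L else th$min_disruptive_indel_residues,
    t7e1MinIndel = if (is.null(th$t7e1_min_indel)) 2L else th$t7e1_min_indel,
    nearTargetWindow = if (is.null(th$near_target_window_bp)) 10L else th$near_target_window_bp)
  list(amplicon = amp, guides = guides, thresholds = thresholds)
}

#' Export amplicon annotation as BED
#'
#' Writes the exon, introns and splice windows as a 4-column BED file
#' (0-based half-open, the BED convention).
#'
#' @param amplicon an \code{\link{Amplicon-class}}.
#' @param file output path.
#' @return The path, invisibly.
#' @export
writeBed <- function(amplicon, file) {
  stopifnot(is(amplicon, "Amplicon"))
  ivs <- list(intron5 = amplicon@intron5, splice5 = amplicon@splice5,
              exon = amplicon@exon, splice3 = amplicon@splice3,
              intron3 = amplicon@intron3)
  df <- data.frame(chrom = amplicon@id,
                   chromStart = vapply(ivs, start, 1L) - 1L,
                   chromEnd = vapply(ivs, end, 1L),
                   name = names(ivs))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' Read and write FASTQ files
#'
#' Thin wrappers around Biostrings' quality-aware FASTQ support. Files
#' ending in \code{.gz} are read/written gzip-compressed.
#'
#' @param file FASTQ path (plain or gzip).
#' @param reads a \code{QualityScaledDNAStringSet} (Phred+33).
#' @return \code{readFastq}: a \code{QualityScaledDNAStringSet};
#'   \code{writeFastq}: the path, invisibly.
#' @examples
#' toy <- makeToyAmplicon(seed = 1)
#' sim <- simulateReads(toy$amplicon, toy$guide,
#'                      simulationConfig(nReads = 5, seed = 1))
#' f <- tempfile(fileext = ".fastq")
#' writeFastq(sim$reads1, f)
#' readFastq(f)
#' @export
readFastq <- function(file) {
  if (!file.exists(file)) stop("FASTQ file not found: ", file)
  # Biostrings warns about dropping its own internal metadata columns here;
  # nothing user-visible is lost
  withCallingHandlers(
    readQualityScaledDNAStringSet(file),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' @rdname readFastq
#' @export
writeFastq <- function(reads, file) {
  stopifnot(is(reads, "QualityScaledDNAStringSet"))
  writeQualityScaledXStringSet(reads, file,
                               compress = grepl("\\.gz$", file))
  invisible(file)
}
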