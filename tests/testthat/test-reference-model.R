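test_that("consistent annotation constructs a valid Amplicon", {
  set.seed(11)
  seq <- randSeq(300)
  amp <- Amplicon(seq, exon = c(101, 200), intron5 = c(1, 100),
                  intron3 = c(201, 300), splice5 = c(89, 100),
                  splice3 = c(201, 212))
  expect_s4_class(amp, "Amplicon")
  expect_identical(as.character(ampliconSeq(amp)), seq)
  expect_equal(start(exonRegion(amp)), 101)
  expect_equal(end(spliceWindow(amp, "5")) + 1L, start(exonRegion(amp)))
})

test_that("inconsistent annotation is rejected, naming the offender", {
  set.seed(12)
  seq <- randSeq(300)
  # exon overlapping intron5
  expect_error(
    Amplicon(seq, exon = c(101, 200), intron5 = c(150, 160),
             intron3 = c(201, 300), splice5 = c(89, 100),
             splice3 = c(201, 212)),
    "intron5")
  # splice5 window not abutting the exon
  expect_error(
    Amplicon(seq, exon = c(101, 200), intron5 = c(1, 100),
             intron3 = c(201, 300), splice5 = c(80, 91),
             splice3 = c(201, 212)),
    "splice5")
  # out of bounds
  expect_error(
    Amplicon(seq, exon = c(101, 200), intron5 = c(1, 100),
             intron3 = c(201, 350), splice5 = c(89, 100),
             splice3 = c(201, 212)),
    "intron3")
  # bad alphabet
  expect_error(
    Amplicon(gsub("A", "U", seq), exon = c(101, 200), intron5 = c(1, 100),
             intron3 = c(201, 300), splice5 = c(89, 100),
             splice3 = c(201, 212)))
})

makeGuideAmplicon <- function(core, offset, strand = "+", n = 300) {
  # embed protospacer+TGG (or its revcomp) at `offset` in random sequence
  insert <- if (strand == "+") paste0(core, "TGG") else revcomp(paste0(core, "TGG"))
  repeat {
    seq <- randSeq(n)
    substr(seq, offset, offset + nchar(insert) - 1L) <- insert
    amp <- Amplicon(seq, exon = c(101, 200), intron5 = c(1, 100),
                    intron3 = c(201, n), splice5 = c(89, 100),
                    splice3 = c(201, 212))
    g <- tryCatch(locateGuide(amp, core), error = function(e) NULL)
    if (!is.null(g)) return(list(amp = amp, guide = g))
  }
}

test_that("locateGuide recovers a plus-strand construction exactly", {
  set.seed(21)
  core <- randSeq(20)
  fx <- makeGuideAmplicon(core, offset = 51, strand = "+")
  expect_equal(fx$guide@strand, "+")
  expect_equal(fx$guide@start, 51L)   # 0-based 50 in half-open terms
  expect_equal(cutSite(fx$guide), 67L)  # 3 bp 5' of the PAM
  expect_equal(fx$guide@pam, "TGG")
})

test_that("locateGuide finds reverse-strand guides, agreeing with a brute scan", {
  set.seed(22)
  core <- randSeq(20)
  fx <- makeGuideAmplicon(core, offset = 51, strand = "-")
  expect_equal(fx$guide@strand, "-")

  # brute-force scan of both strands for core+NGG
  seq <- as.character(ampliconSeq(fx$amp))
  hits <- list()
  for (p in 1:(nchar(seq) - 22)) {
    w <- substr(seq, p, p + 22)
    if (substr(w, 1, 20) == core && substr(w, 22, 23) == "GG")
      hits[[length(hits) + 1]] <- list(strand = "+", start = p, cut = p + 16)
    rcw <- revcomp(w)
    if (substr(rcw, 1, 20) == core && substr(rcw, 22, 23) == "GG")
      hits[[length(hits) + 1]] <- list(strand = "-", start = p + 3,
                                       cut = p + 3 + 2)
  }
  expect_length(hits, 1)
  expect_equal(fx$guide@start, hits[[1]]$start)
  expect_equal(cutSite(fx$guide), hits[[1]]$cut)
})

test_that("locateGuide errors on absent and ambiguous protospacers", {
  set.seed(23)
  seq <- randSeq(300)
  amp <- Amplicon(seq, exon = c(101, 200), intron5 = c(1, 100),
                  intron3 = c(201, 300), splice5 = c(89, 100),
                  splice3 = c(201, 212))
  expect_error(locateGuide(amp, paste(rep("ACGT", 5), collapse = "")),
               "not found")
  core <- randSeq(20)
  dup <- seq
  substr(dup, 11, 33) <- paste0(core, "AGG")
  substr(dup, 241, 263) <- paste0(core, "TGG")
  amp2 <- Amplicon(dup, exon = c(101, 200), intron5 = c(1, 100),
                   intron3 = c(201, 300), splice5 = c(89, 100),
                   splice3 = c(201, 212))
  expect_error(locateGuide(amp2, core), "ambiguous")
  expect_error(locateGuide(amp, "ACGT"), "20-nt")
})

test_that("guide localization round-trips construction offsets on both strands", {
  set.seed(24)
  for (rep in 1:10) {
    core <- randSeq(20)
    offset <- sample(5:270, 1)
    strand <- sample(c("+", "-"), 1)
    fx <- makeGuideAmplicon(core, offset = offset, strand = strand)
    if (strand == "+") {
      expect_equal(fx$guide@start, offset)
      expect_equal(cutSite(fx$guide), offset + 16L)
    } else {
      # reverse-complemented insert: PAM occupies the first 3 bases
      expect_equal(fx$guide@start, offset + 3L)
      expect_equal(cutSite(fx$guide), offset + 5L)
    }
    expect_equal(protospacerSeq(fx$guide), core)
  }
})

test_that("threshold and scoring constructors validate their arguments", {
  th <- editThresholds()
  expect_equal(th@spliceChangeMax, 1L)
  expect_equal(th@residueChangeMax, 5L)
  expect_equal(th@t7e1MinIndel, 2L)
  expect_error(editThresholds(spliceChangeMax = -1), ">= 0")
  sc <- alignScoring()
  expect_equal(sc@gapOpen, -12L)
  expect_error(alignScoring(mismatch = 1))
})

test_that("config round-trip builds the same amplicon and exports BED", {
  toy <- toyFixture()
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "ref.fasta")
  writeLines(c(">toy", as.character(ampliconSeq(toy$amplicon))), fa)
  cfg <- list(fasta = fa,
              exon = c(151, 300), intron5 = c(1, 150),
              intron3 = c(301, 440), splice5 = c(139, 150),
              splice3 = c(301, 312), frame_offset = 0,
              guides = list(protospacerSeq(toy$guide)))
  built <- ampliconFromConfig(cfg)
  expect_equal(as.character(ampliconSeq(built$amplicon)),
               as.character(ampliconSeq(toy$amplicon)))
  expect_equal(cutSite(built$guides[[1]]), cutSite(toy$guide))

  bed <- file.path(dir, "regions.bed")
  writeBed(built$amplicon, bed)
  lines <- read.table(bed, sep = "\t")
  expect_equal(lines$V2[lines$V4 == "exon"], 150)   # BED is 0-based
  expect_equal(lines$V3[lines$V4 == "exon"], 300)
})
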