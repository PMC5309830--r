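ev1 <- function(kind, start, len, alt = if (kind == "deletion") "" else
                  strrep("A", len), id = "r") {
  data.frame(readId = id, kind = kind, start = as.integer(start),
             length = as.integer(len), alt = alt, stringsAsFactors = FALSE)
}

test_that("coding-impact categories follow the length-mod-3 exon rule", {
  toy <- toyFixture()
  es <- start(exonRegion(toy$amplicon))  # 151
  expect_equal(classifyCodingImpact(ev1("deletion", es + 10, 1), toy$amplicon),
               "frameshift")
  expect_equal(classifyCodingImpact(ev1("deletion", es + 10, 3), toy$amplicon),
               "in_frame")
  expect_equal(classifyCodingImpact(ev1("insertion", 50, 2), toy$amplicon),
               "noncoding")
  expect_equal(classifyCodingImpact(ev1("deletion", 20, 6), toy$amplicon),
               "noncoding")
  expect_equal(
    classifyCodingImpact(ev1("deletion", 20, 6)[0, ], toy$amplicon),
    "unmodified")
  # deletion straddling the exon start: only exonic bases count
  expect_equal(
    classifyCodingImpact(ev1("deletion", es - 2, 6), toy$amplicon),
    ifelse(4 %% 3 == 0, "in_frame", "frameshift"))
  # net frame over multiple indels: +1 insertion and -1 deletion cancel
  both <- rbind(ev1("insertion", es + 10, 1), ev1("deletion", es + 40, 1))
  expect_equal(classifyCodingImpact(both, toy$amplicon), "in_frame")
  # exonic substitution-only read: modified but not frameshift
  expect_equal(classifyCodingImpact(ev1("substitution", es + 10, 2, "AA"),
                                    toy$amplicon), "in_frame")
})

test_that("insertion junctions at exon boundaries are not exon-internal", {
  toy <- toyFixture()
  es <- start(exonRegion(toy$amplicon)); ee <- end(exonRegion(toy$amplicon))
  # inserted before the first exon base: upstream of the coding sequence
  expect_equal(classifyCodingImpact(ev1("insertion", es, 2), toy$amplicon),
               "noncoding")
  # inserted after the last exon base
  expect_equal(classifyCodingImpact(ev1("insertion", ee + 1, 2), toy$amplicon),
               "noncoding")
  # strictly inside
  expect_equal(classifyCodingImpact(ev1("insertion", es + 1, 2), toy$amplicon),
               "frameshift")
})

test_that("splice-change counts equal direct window arithmetic", {
  toy <- toyFixture()
  w5 <- spliceWindow(toy$amplicon, "5")  # [139, 150]
  expect_equal(countSpliceChanges(ev1("deletion", 200, 3), w5), 0)
  expect_equal(countSpliceChanges(ev1("substitution", start(w5) + 2, 1, "A"),
                                  w5), 1)
  expect_equal(countSpliceChanges(ev1("deletion", start(w5) + 4, 4), w5), 4)
  # deletion overhanging the window: only window bases count
  expect_equal(countSpliceChanges(ev1("deletion", start(w5) - 3, 6), w5), 3)
  # insertions strictly inside vs at the window edge
  expect_equal(countSpliceChanges(ev1("insertion", start(w5) + 1, 5), w5), 5)
  expect_equal(countSpliceChanges(ev1("insertion", start(w5), 5), w5), 0)
})

test_that("protein consequence matches an independent translate-and-compare", {
  toy <- toyFixture()
  amp <- toy$amplicon
  ref <- as.character(ampliconSeq(amp))
  es <- start(exonRegion(amp)); ee <- end(exonRegion(amp))

  # no events
  pc0 <- proteinConsequence(ev1("deletion", 1, 1)[0, ], amp)
  expect_false(pc0$prematureStop)
  expect_equal(pc0$residueChanges, 0L)

  # in-frame deletion of exactly one codon (codon-aligned)
  del3 <- ev1("deletion", es + 3, 3)
  pc3 <- proteinConsequence(del3, amp)
  expect_false(pc3$prematureStop)
  expect_equal(pc3$residueChanges, 1L)

  # 1-nt deletion early in the exon: frameshift; compare against brute-force
  # translation of the reconstructed mutant read through the downstream
  # reference
  del1 <- ev1("deletion", es + 4, 1)
  pc1 <- proteinConsequence(del1, amp)
  refPep <- translateOracle(substr(ref, es, ee))
  mut <- applyEventsOracle(ref, del1)
  mutTail <- substr(mut, es, nchar(mut))
  mutPepFull <- translateOracle(mutTail)
  stopAt <- regexpr("*", mutPepFull, fixed = TRUE)
  oracleStop <- stopAt > 0
  oraclePep <- if (oracleStop) substr(mutPepFull, 1, stopAt - 1) else mutPepFull
  expect_equal(pc1$prematureStop, oracleStop)
  expect_equal(pc1$residueChanges,
               as.integer(adist(refPep, oraclePep)))

  # substitution creating a stop codon in-frame
  codonStart <- es + 9
  stopEv <- ev1("substitution", codonStart, 3, "TAA")
  pcS <- proteinConsequence(stopEv, amp)
  expect_true(pcS$prematureStop)
  expect_equal(pcS$residueChanges,
               as.integer(adist(refPep, substr(refPep, 1, 3))))
})

test_that("protein consequence handles random exonic indels like the oracle", {
  set.seed(71)
  toy <- toyFixture()
  amp <- toy$amplicon
  ref <- as.character(ampliconSeq(amp))
  es <- start(exonRegion(amp)); ee <- end(exonRegion(amp))
  for (i in 1:25) {
    kind <- sample(c("deletion", "insertion"), 1)
    L <- sample(1:12, 1)
    st <- sample((es + 1):(ee - 15), 1)
    ev <- if (kind == "deletion") ev1("deletion", st, L) else
      ev1("insertion", st, L, randSeq(L))
    pc <- proteinConsequence(ev, amp)

    refPep <- translateOracle(substr(ref, es, ee))
    mut <- applyEventsOracle(ref, ev)
    netL <- if (kind == "insertion") L else
      -(min(st + L - 1, ee) - max(st, es) + 1)
    mutEe <- ee + netL
    tail <- if (netL %% 3 == 0) substr(mut, es, mutEe) else
      substr(mut, es, nchar(mut))
    pep <- translateOracle(tail)
    stopAt <- regexpr("*", pep, fixed = TRUE)
    oPep <- if (stopAt > 0) substr(pep, 1, stopAt - 1) else pep
    expect_equal(pc$prematureStop, stopAt > 0, info = paste("case", i))
    expect_equal(pc$residueChanges, as.integer(adist(refPep, oPep)),
                 info = paste("case", i))
  }
})

test_that("the disruptive rule applies thresholds and exclusions exactly", {
  out <- data.frame(
    splice5Changes = c(2L, 1L, 0L, 0L, 0L, 0L),
    splice3Changes = c(0L, 0L, 5L, 0L, 0L, 0L),
    codingIndel    = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    prematureStop  = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    residueChanges = c(0L, 0L, 0L, 3L, 2L, 6L))
  # 1: >1 splice5 change -> disruptive
  # 2: single splice5 change -> not (threshold is "greater than one")
  # 3: splice3-only changes are excluded
  # 4: substitution-only read (no coding indel) -> excluded even with
  #    residue changes
  # 5: coding indel with premature stop -> disruptive
  # 6: in-frame indel changing 6 residues -> disruptive (> 5)
  expect_equal(isDisruptive(out),
               c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  # in-frame indel affecting exactly 5 residues is excluded
  out5 <- data.frame(splice5Changes = 0L, codingIndel = TRUE,
                     prematureStop = FALSE, residueChanges = 5L)
  expect_false(isDisruptive(out5))
})

test_that("T7E1 detectability needs an indel of at least 2 nt", {
  ev <- rbind(ev1("insertion", 10, 1, "A", id = "a"),
              ev1("deletion", 10, 2, id = "b"),
              ev1("substitution", 10, 4, "ACGT", id = "c"))
  expect_equal(t7e1Detectable(ev),
               c(a = FALSE, b = TRUE, c = FALSE))
})

test_that("every filter-passing read gets exactly one category that sums to one", {
  set.seed(72)
  toy <- toyFixture()
  sim <- simulateReads(toy$amplicon, toy$guide,
                       simulationConfig(nReads = 300, subErrorRate = 0.002,
                                        seed = 9))
  m <- mergePairs(sim$reads1, sim$reads2)
  aln <- alignReads(m$reads, toy$amplicon)
  out <- classifyReads(aln, toy$amplicon)
  expect_true(all(out$category %in%
                    c("unmodified", "frameshift", "in_frame", "noncoding")))
  keep <- out[out$passesFilter, ]
  expect_equal(sum(keep$category == "unmodified"), sum(!keep$modified))
  expect_equal(
    sum(keep$category %in% c("frameshift", "in_frame", "noncoding")),
    sum(keep$modified))
  # unmodified reads carry zero counts and FALSE flags
  un <- keep[!keep$modified, ]
  expect_true(all(un$splice5Changes == 0 & un$splice3Changes == 0 &
                    !un$prematureStop & un$residueChanges == 0 &
                    !un$disruptive & !un$t7e1Detectable))
  # disruptive implies modified
  expect_true(all(!keep$disruptive | keep$modified))
})

test_that("adding a disruptive event never un-sets disruptive", {
  toy <- toyFixture()
  es <- start(exonRegion(toy$amplicon))
  base <- ev1("deletion", es + 10, 3)          # in-frame, 1 residue: benign
  expect_false(isDisruptive(cbind(
    indelScope:::.perReadEventStats(base, toy$amplicon, "r"),
    prematureStop = proteinConsequence(base, toy$amplicon)$prematureStop,
    residueChanges = proteinConsequence(base, toy$amplicon)$residueChanges)))
  w5 <- spliceWindow(toy$amplicon, "5")
  added <- rbind(ev1("deletion", start(w5) + 2, 4), base)
  stats <- indelScope:::.perReadEventStats(added, toy$amplicon, "r")
  pc <- proteinConsequence(added, toy$amplicon)
  expect_true(isDisruptive(cbind(stats, prematureStop = pc$prematureStop,
                                 residueChanges = pc$residueChanges)))
})
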