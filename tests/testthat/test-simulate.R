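test_that("toy amplicons satisfy the structural contract across seeds", {
  for (seed in c(1, 7, 19)) {
    toy <- makeToyAmplicon(seed = seed)
    amp <- toy$amplicon
    expect_true(validObject(amp))
    # 5' splice window carries the donor motif
    expect_equal(as.character(ampliconSeq(amp)[spliceWindow(amp, "5")]),
                 "TTAAAAGCTTCC")
    # reference exon translates without stop
    exonSeq <- as.character(ampliconSeq(amp)[exonRegion(amp)])
    expect_false(grepl("*", translateOracle(exonSeq), fixed = TRUE))
    # exactly one guide hit, by construction
    g <- locateGuide(amp, protospacerSeq(toy$guide))
    expect_equal(cutSite(g), cutSite(toy$guide))
    # cut falls inside the exon, near its 5' end
    expect_gt(cutSite(g), start(exonRegion(amp)))
    expect_lt(cutSite(g), start(exonRegion(amp)) + 30)
  }
  # different seeds, different sequences
  expect_false(as.character(ampliconSeq(makeToyAmplicon(seed = 2)$amplicon)) ==
                 as.character(ampliconSeq(makeToyAmplicon(seed = 3)$amplicon)))
})

test_that("simulation is byte-deterministic under a fixed seed", {
  toy <- toyFixture()
  cfg <- simulationConfig(nReads = 50, seed = 99)
  a <- simulateReads(toy$amplicon, toy$guide, cfg)
  b <- simulateReads(toy$amplicon, toy$guide, cfg)
  expect_identical(as.character(a$reads1), as.character(b$reads1))
  expect_identical(as.character(a$reads2), as.character(b$reads2))
  expect_identical(a$manifest, b$manifest)
  c <- simulateReads(toy$amplicon, toy$guide,
                     simulationConfig(nReads = 50, seed = 100))
  expect_false(identical(as.character(a$reads1), as.character(c$reads1)))
})

test_that("the edited-read count is deterministic and exact", {
  toy <- toyFixture()
  sim <- simulateReads(toy$amplicon, toy$guide,
                       simulationConfig(nReads = 1000, editedFraction = 0.5,
                                        subErrorRate = 0, seed = 4))
  expect_equal(sum(sim$manifest$edited), 500)
  expect_equal(nrow(sim$manifest), 1000)
  # manifest truth fractions are exact ratios of manifest rows
  expect_equal(sim$truth$pctModified, 50)
  expect_equal(sim$truth$pctDisruptive,
               100 * mean(sim$manifest$disruptive))
})

test_that("an unedited error-free control is the pure reference", {
  toy <- toyFixture()
  ref <- as.character(ampliconSeq(toy$amplicon))
  sim <- simulateReads(toy$amplicon, toy$guide,
                       simulationConfig(nReads = 30, editedFraction = 0,
                                        subErrorRate = 0, seed = 5))
  expect_true(all(as.character(sim$reads1) == substr(ref, 1, 300)))
  expect_true(all(as.character(sim$reads2) ==
                    revcomp(substr(ref, 141, 440))))
  expect_true(all(!sim$manifest$edited))
  expect_equal(sim$truth$pctModified, 0)
  # and the pipeline agrees: no modified reads at all
  res <- analyzeSample(sim$reads1, sim$reads2, toy$amplicon, toy$guide,
                       sampleId = "ctrl0")
  expect_equal(res$summary@pctModified, 0)
  expect_equal(res$summary@nPassFilter, 30L)
})

test_that("planted indel sizes respect the configured support", {
  toy <- toyFixture()
  sim <- simulateReads(toy$amplicon, toy$guide,
                       simulationConfig(nReads = 400, editedFraction = 1,
                                        subErrorRate = 0, seed = 6))
  sz <- abs(sim$manifest$size[sim$manifest$edited])
  expect_true(all(sz >= 1 & sz <= 50))
  # both kinds occur, deletions dominate at the default insertion:deletion mix
  expect_gt(sum(sim$manifest$kind == "deletion", na.rm = TRUE),
            sum(sim$manifest$kind == "insertion", na.rm = TRUE))
})

test_that("planted events are left-normalized against the reference", {
  toy <- toyFixture()
  ref <- as.character(ampliconSeq(toy$amplicon))
  sim <- simulateReads(toy$amplicon, toy$guide,
                       simulationConfig(nReads = 200, editedFraction = 1,
                                        subErrorRate = 0, seed = 8))
  m <- sim$manifest[sim$manifest$edited, ]
  for (i in seq_len(nrow(m))) {
    st <- m$start[i]; L <- abs(m$size[i])
    if (m$kind[i] == "deletion") {
      if (st > 1)
        expect_false(substr(ref, st - 1, st - 1) ==
                       substr(ref, st + L - 1, st + L - 1))
    } else if (st > 1) {
      expect_false(substr(ref, st - 1, st - 1) == substr(m$alt[i], L, L))
    }
  }
})

test_that("manifest truth and per-read pipeline outcomes coincide when error-free", {
  toy <- toyFixture()
  sim <- simulateReads(toy$amplicon, toy$guide,
                       simulationConfig(nReads = 150, editedFraction = 0.4,
                                        subErrorRate = 0, seed = 10))
  res <- analyzeSample(sim$reads1, sim$reads2, toy$amplicon, toy$guide,
                       sampleId = "exact")
  out <- res$outcomes[match(sim$manifest$readId, res$outcomes$readId), ]
  expect_equal(out$modified, sim$manifest$edited)
  expect_equal(out$category, sim$manifest$category)
  expect_equal(out$splice5Changes, sim$manifest$splice5Changes)
  expect_equal(out$prematureStop, sim$manifest$prematureStop)
  expect_equal(out$residueChanges, sim$manifest$residueChanges)
  expect_equal(out$disruptive, sim$manifest$disruptive)
  expect_equal(out$t7e1Detectable, sim$manifest$t7e1Detectable)
})
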