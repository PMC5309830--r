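test_that("region filter requires coverage of splice window plus exon", {
  toy <- toyFixture()
  ref <- as.character(ampliconSeq(toy$amplicon))
  # splice5 [139,150], exon [151,300]
  reads <- c(full = substr(ref, 1, 440),
             exact = substr(ref, 139, 300),
             missesSplice = substr(ref, 151, 440),
             missesExonEnd = substr(ref, 100, 290))
  aln <- alignReads(reads, toy$amplicon)
  expect_equal(unname(passesRegionFilter(aln, toy$amplicon)),
               c(TRUE, TRUE, FALSE, FALSE))
})

test_that("a splice-window deletion is a mutation, not a filter failure", {
  toy <- toyFixture()
  ref <- as.character(ampliconSeq(toy$amplicon))
  # delete 6 nt inside the splice window from an otherwise full-span read
  q <- paste0(substr(ref, 1, 140), substr(ref, 147, 440))
  aln <- alignReads(c(r = q), toy$amplicon)
  expect_true(unname(passesRegionFilter(aln, toy$amplicon)))
  # ... but the literal-motif variant excludes it
  expect_false(unname(passesRegionFilter(aln, toy$amplicon,
                                         requireMotif = TRUE, reads = q)))
  expect_true(unname(passesRegionFilter(
    alignReads(c(r = ref), toy$amplicon), toy$amplicon,
    requireMotif = TRUE, reads = ref)))
})

test_that("extending a read's span never un-passes the region filter", {
  set.seed(61)
  toy <- toyFixture()
  ref <- as.character(ampliconSeq(toy$amplicon))
  for (i in 1:15) {
    s <- sample(1:150, 1); e <- sample(290:440, 1)
    base <- passesRegionFilter(
      alignReads(substr(ref, s, e), toy$amplicon), toy$amplicon)
    ext <- passesRegionFilter(
      alignReads(substr(ref, max(1, s - 10), min(440, e + 10)),
                 toy$amplicon), toy$amplicon)
    if (base) expect_true(unname(ext))
  }
})

test_that("indel size histogram counts constructed reads correctly", {
  ev <- data.frame(
    readId = c("d1", "d2", "d3", "i1", "i2"),
    kind = c(rep("deletion", 3), rep("insertion", 2)),
    start = 10L, length = c(3L, 3L, 3L, 1L, 1L),
    alt = c("", "", "", "A", "T"), stringsAsFactors = FALSE)
  ids <- c(paste0("d", 1:3), paste0("i", 1:2), paste0("clean", 1:5))
  h <- indelSizeDistribution(ev, ids)
  expect_equal(h$count[h$size == -3], 3)
  expect_equal(h$count[h$size == 1], 2)
  expect_equal(h$count[h$size == 0], 5)
  expect_equal(sum(h$count), 10)
  # all-unmodified sample: all mass at zero
  h0 <- indelSizeDistribution(ev[0, ], ids)
  expect_equal(h0, data.frame(size = 0L, count = 10L))
  # substitution-only reads land in the zero bin
  evs <- data.frame(readId = "s1", kind = "substitution", start = 5L,
                    length = 2L, alt = "AA", stringsAsFactors = FALSE)
  hs <- indelSizeDistribution(evs, c("s1", "s2"))
  expect_equal(hs, data.frame(size = 0L, count = 2L))
})

test_that("positional profile increments covered and junction positions", {
  toy <- toyFixture()
  ev <- data.frame(readId = c("a", "b", "c"),
                   kind = c("deletion", "insertion", "substitution"),
                   start = c(150L, 200L, 250L), length = c(3L, 4L, 2L),
                   alt = c("", "ACGT", "AA"), stringsAsFactors = FALSE)
  prof <- positionalProfile(ev, toy$amplicon)
  expect_equal(prof$deletion[150:152], rep(1L, 3))
  expect_equal(sum(prof$deletion), 3)
  expect_equal(prof$insertion[200], 1L)
  expect_equal(sum(prof$insertion), 1)
  expect_equal(prof$substitution[250:251], rep(1L, 2))
  # empty control: flat zero
  p0 <- positionalProfile(ev[0, ], toy$amplicon)
  expect_true(all(p0$deletion == 0 & p0$insertion == 0 & p0$substitution == 0))
})

test_that("event-to-cut distances use the nearest edge", {
  toy <- toyFixture()
  cut <- cutSite(toy$guide)  # junction after base `cut`
  ev <- data.frame(
    readId = c("cover", "leftOf", "rightOf", "insAt", "insFar"),
    kind = c("deletion", "deletion", "deletion", "insertion", "insertion"),
    start = c(cut - 2L, cut - 9L, cut + 7L, cut + 1L, cut + 21L),
    length = c(6L, 4L, 3L, 2L, 2L),
    alt = c("", "", "", "AA", "TT"), stringsAsFactors = FALSE)
  d <- eventCutDistance(ev, toy$guide)
  # deletion covering the cut: 0; ending 6 left of it: 6; starting 6 right: 6
  expect_equal(unname(d), c(0L, 6L, 6L, 0L, 20L))
  expect_equal(nearCutFraction(ev, toy$guide, window = 10), 0.8)
})

test_that("reconstruction invariant: events applied to the reference give the read", {
  set.seed(62)
  toy <- toyFixture()
  ref <- as.character(ampliconSeq(toy$amplicon))
  for (i in 1:25) {
    # plant 1-3 well-separated random events
    k <- sample(1:3, 1)
    starts <- sort(sample(seq(30, 380, by = 60), k))
    evs <- do.call(rbind, lapply(starts, function(st) {
      kind <- sample(c("deletion", "insertion", "substitution"), 1)
      L <- sample(1:8, 1)
      alt <- switch(kind, deletion = "", insertion = randSeq(L),
                    substitution = {
                      repeat {
                        a <- randSeq(L)
                        if (a != substr(ref, st, st + L - 1)) break
                      }
                      a
                    })
      data.frame(readId = "r", kind = kind, start = st, length = L,
                 alt = alt, stringsAsFactors = FALSE)
    }))
    mut <- applyEventsOracle(ref, evs)
    aln <- alignReads(c(r = mut), toy$amplicon)
    got <- alignmentEvents(aln)
    cov <- substr(ref, start(aln@range), end(aln@range))
    gotLocal <- transform(got, start = start - start(aln@range) + 1L)
    expect_identical(applyEventsOracle(cov, gotLocal), mut,
                     info = paste("case", i))
  }
})
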